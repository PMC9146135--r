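# Seeded synthetic data: annotated genomes with planted TI-PKS clusters and
# orthogroup structure, an optional atranorin-like cluster, and alignments
# simulated on known trees. Everything is deterministic given the seed, so
# downstream stages can be tested against an exact ground truth.

# Pfam accessions used for planted accessory genes.
PFAM_P450 <- "PF00067"
PFAM_OMT <- "PF08241"
PFAM_MFS <- "PF07690"
PFAM_WD40 <- "PF00400"
PFAM_NEUTRAL <- c("PF00172", "PF01636", "PF00743", "PF00118",
                  "PF12013", "PF04056", "PF00083")

#' Simulation parameters for synthetic genome bundles
#'
#' Defaults describe a small, fully controlled study: a handful of PKS
#' families shared across genomes (the planted orthogroups), group
#' frequencies proportional to the census class shares (44.35% NR, 53.35%
#' R, 2.3% PR, split across the named groups), high within-family identity
#' and chance-level between-family identity.
#'
#' @param n_genomes Number of genomes (>= 1).
#' @param mean_clusters_per_genome Poisson mean of planted PKS clusters per
#'   genome (truncated at >= 1 so every genome is censusable).
#' @param group_frequencies Named probabilities over registry group names;
#'   must sum to 1.
#' @param within_family_identity Minimum percent identity between members
#'   of one planted family (the generator tunes its substitution rate a
#'   little above this floor and enforces the minimum).
#' @param between_family_identity_ceiling Upper bound on identity between
#'   unrelated families; families descend from independent random
#'   ancestors, whose expected identity is chance level, far below any
#'   sensible ceiling. Must be below `within_family_identity`.
#' @param plant_atranorin_in Integer vector of genome indices (1-based)
#'   that receive one atranorin-like cluster (PKS23-like core plus P450,
#'   O-methyltransferase and transporter genes).
#' @param n_decoy_clusters_mean Poisson mean of non-T1PKS decoy clusters
#'   per genome (NRPS/terpene/T3PKS/other).
#' @param core_length,accessory_length Protein lengths (residues).
#' @param seed Master seed.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_genomes = 3,
                       mean_clusters_per_genome = 3,
                       group_frequencies = c(
                         "PR" = 0.023,
                         "NR-SI" = 0.25, "NR-SII" = 0.12, "NR-IX" = 0.0735,
                         "R" = 0.30, "R-V" = 0.08, "R-IX" = 0.08,
                         "R-X" = 0.0735),
                       within_family_identity = 70,
                       between_family_identity_ceiling = 25,
                       plant_atranorin_in = integer(0),
                       n_decoy_clusters_mean = 1,
                       core_length = 200,
                       accessory_length = 120,
                       seed = 1) {
  if (n_genomes < 1) abort("need at least one genome")
  if (abs(sum(group_frequencies) - 1) > 1e-9) {
    abort("group_frequencies must sum to 1")
  }
  if (any(group_frequencies < 0)) abort("group_frequencies must be non-negative")
  registry <- pks_group_registry()
  unknown <- setdiff(names(group_frequencies), registry$name)
  if (length(unknown) > 0) {
    abort(sprintf("unknown group name(s) in frequencies: %s",
                  paste(unknown, collapse = ", ")))
  }
  if (within_family_identity <= between_family_identity_ceiling) {
    abort("within_family_identity must exceed between_family_identity_ceiling")
  }
  stopifnot(within_family_identity > 0, within_family_identity <= 100)
  if (length(plant_atranorin_in) > 0) {
    stopifnot(all(plant_atranorin_in >= 1),
              all(plant_atranorin_in <= n_genomes))
  }
  structure(
    list(n_genomes = n_genomes,
         mean_clusters_per_genome = mean_clusters_per_genome,
         group_frequencies = group_frequencies,
         within_family_identity = within_family_identity,
         between_family_identity_ceiling = between_family_identity_ceiling,
         plant_atranorin_in = as.integer(plant_atranorin_in),
         n_decoy_clusters_mean = n_decoy_clusters_mean,
         core_length = core_length,
         accessory_length = accessory_length,
         seed = seed),
    class = "sim_params"
  )
}

# Random legal expansion of a grammar pattern: each optional element kept
# with probability 1/2, alternatives chosen uniformly.
sample_expansion <- function(pattern) {
  if (is.character(pattern)) pattern <- parse_pattern(pattern)
  toks <- character(0)
  for (el in pattern) {
    if (el$optional && stats::runif(1) < 0.5) next
    toks <- c(toks, sample(el$tokens, 1))
  }
  toks
}

# Per-site identity between two equal-length sequences.
per_site_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  100 * mean(ca == cb)
}

# Generate family members (one per requested genome) from a common
# ancestor, regenerating until the minimum pairwise per-site identity
# reaches the floor.
make_family_members <- function(ancestor, n, q, floor_identity,
                                max_attempts = 25) {
  for (attempt in seq_len(max_attempts)) {
    members <- vapply(seq_len(n), function(i) mutate_protein(ancestor, q), "")
    if (n == 1) return(members)
    ok <- TRUE
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (per_site_identity(members[i], members[j]) < floor_identity) {
          ok <- FALSE
          break
        }
      }
      if (!ok) break
    }
    if (ok) return(members)
  }
  abort("could not reach the requested within-family identity")
}

#' Generate synthetic annotated genomes with planted truth
#'
#' Plants a set of TI-PKS families shared across genomes (the true
#' orthogroups): each family carries a group label drawn from
#' `group_frequencies`, a concrete domain architecture sampled as a legal
#' expansion of that group's grammar, and a random ancestral protein from
#' which each genome's member is derived by per-site substitution at a
#' rate tuned (by bisection on the expected identity) to sit a few points
#' above the requested within-family identity floor, which is then
#' enforced exactly. Genomes additionally receive decoy non-PKS clusters,
#' and selected genomes one atranorin-like cluster: a PKS23-like core
#' (derived from the packaged synthetic reference) plus cytochrome P450
#' (PF00067), O-methyltransferase (PF08241) and MFS transporter (PF07690)
#' genes. Identical parameters (including the seed) reproduce the output
#' byte for byte.
#'
#' @param params A [sim_params()].
#' @return List with `genomes` (list of [genome_annotation()]) and `truth`
#'   (a `truth_bundle`: `genes`, `orthogroups`, `atranorin_clusters`,
#'   `tree_newick`).
#' @export
gen_genomes <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  registry <- pks_group_registry()
  withr::with_seed(derive_seed(params$seed, "genomes"), {
    freqs <- params$group_frequencies
    n_fam <- max(2, ceiling(params$mean_clusters_per_genome * 2))
    fam_ids <- sprintf("FAM%02d", seq_len(n_fam))
    fam_group <- sample(names(freqs), n_fam, replace = TRUE, prob = freqs)
    fam_arch <- vapply(fam_group, function(g) {
      paste(sample_expansion(registry$pattern[registry$name == g]),
            collapse = "-")
    }, "")
    fam_ancestor <- vapply(seq_len(n_fam),
                           function(i) random_protein(params$core_length), "")

    target_identity <- min(0.99, params$within_family_identity / 100 + 0.05)
    q_within <- identity_to_subst_rate(target_identity)
    # single-lineage rate for the atranorin core vs the fixed reference:
    # substitutions always change the residue, so identity is 1 - q
    q_atr <- 1 - 0.72

    genome_ids <- sprintf("genome%02d", seq_len(params$n_genomes))

    # which families occur in which genome
    fam_use <- lapply(seq_len(params$n_genomes), function(i) {
      k <- 0
      while (k < 1) k <- rpois(1, params$mean_clusters_per_genome)
      k <- min(k, n_fam)
      sort(sample.int(n_fam, k))
    })

    # family members per genome, identity floor enforced
    members <- vector("list", n_fam)
    for (f in seq_len(n_fam)) {
      uses <- which(vapply(fam_use, function(u) f %in% u, TRUE))
      if (length(uses) == 0) next
      m <- make_family_members(fam_ancestor[f], length(uses), q_within,
                               params$within_family_identity)
      members[[f]] <- setNames(m, genome_ids[uses])
    }

    reference <- pks23_reference()[[1]]
    nr_ix_pattern <- registry$pattern[registry$name == "NR-IX"]

    truth_genes <- list()
    truth_og <- list()
    atr_clusters <- character(0)
    genomes <- vector("list", params$n_genomes)

    for (i in seq_len(params$n_genomes)) {
      gid <- genome_ids[i]
      genes <- list()
      clusters <- list()
      proteome <- character(0)
      cursor <- 1L
      gene_no <- 0L

      add_gene <- function(cluster_id, protein, pfam, domains, product,
                           is_core) {
        gene_no <<- gene_no + 1L
        gene_id <- sprintf("%s_g%04d", gid, gene_no)
        glen <- 3L * nchar(protein)
        genes[[length(genes) + 1L]] <<- tibble(
          gene_id = gene_id, contig = "ctg1",
          start = cursor, end = cursor + glen - 1L,
          strand = sample(c("+", "-"), 1),
          pfam = pfam, domains = domains, product = product,
          cluster_id = cluster_id
        )
        cursor <<- cursor + glen + 500L
        proteome[gene_id] <<- protein
        gene_id
      }

      add_cluster <- function(type_label, core_protein, core_pfam,
                              core_domains, core_product, accessories) {
        cid <- sprintf("%s_c%02d", gid, length(clusters) + 1L)
        core_id <- add_gene(cid, core_protein, core_pfam, core_domains,
                            core_product, TRUE)
        for (acc in accessories) {
          add_gene(cid, acc$protein, acc$pfam, NA_character_, acc$product,
                   FALSE)
        }
        cursor <<- cursor + 5000L
        clusters[[length(clusters) + 1L]] <<- tibble(
          cluster_id = cid, type_label = type_label, core_gene_ids = core_id
        )
        cid
      }

      random_accessories <- function(n) {
        lapply(seq_len(n), function(j) {
          list(protein = random_protein(params$accessory_length),
               pfam = sample(PFAM_NEUTRAL, 1),
               product = "hypothetical protein")
        })
      }

      # planted PKS clusters, one per family used by this genome
      for (f in fam_use[[i]]) {
        cid <- add_cluster(
          "T1PKS",
          core_protein = members[[f]][[gid]],
          core_pfam = "PF00109,PF00698",
          core_domains = fam_arch[f],
          core_product = sprintf("polyketide synthase (%s)", fam_group[f]),
          accessories = random_accessories(sample(1:3, 1))
        )
        core_id <- clusters[[length(clusters)]]$core_gene_ids
        truth_genes[[length(truth_genes) + 1L]] <- tibble(
          gene_id = core_id, genome = gid, family = fam_ids[f],
          group = fam_group[f], cluster_id = cid, role = "pks_core"
        )
        truth_og[[length(truth_og) + 1L]] <- tibble(
          member = core_id, family = fam_ids[f]
        )
      }

      # atranorin-like cluster
      if (i %in% params$plant_atranorin_in) {
        core <- mutate_protein(reference, q_atr)
        cid <- add_cluster(
          "T1PKS",
          core_protein = core,
          core_pfam = "PF00109,PF00698",
          core_domains = paste(sample_expansion(nr_ix_pattern), collapse = "-"),
          core_product = "polyketide synthase PKS23-like",
          accessories = list(
            list(protein = random_protein(params$accessory_length),
                 pfam = PFAM_P450, product = "cytochrome P450"),
            list(protein = random_protein(params$accessory_length),
                 pfam = PFAM_OMT, product = "O-methyltransferase"),
            list(protein = random_protein(params$accessory_length),
                 pfam = PFAM_MFS, product = "MFS transporter")
          )
        )
        core_id <- clusters[[length(clusters)]]$core_gene_ids
        atr_clusters <- c(atr_clusters, cid)
        truth_genes[[length(truth_genes) + 1L]] <- tibble(
          gene_id = core_id, genome = gid, family = "FAM_ATR",
          group = "NR-IX", cluster_id = cid, role = "atranorin_core"
        )
        truth_og[[length(truth_og) + 1L]] <- tibble(
          member = core_id, family = "FAM_ATR"
        )
      }

      # decoy non-T1PKS clusters
      n_decoy <- rpois(1, params$n_decoy_clusters_mean)
      for (d in seq_len(n_decoy)) {
        add_cluster(
          sample(c("NRPS", "terpene", "T3PKS", "other"), 1),
          core_protein = random_protein(params$accessory_length),
          core_pfam = sample(PFAM_NEUTRAL, 1),
          core_domains = NA_character_,
          core_product = "secondary metabolite core",
          accessories = random_accessories(sample(0:2, 1))
        )
      }

      genomes[[i]] <- genome_annotation(
        genome = gid,
        genes = dplyr::bind_rows(genes),
        clusters = dplyr::bind_rows(clusters),
        proteome = proteome
      )
    }

    tree <- ape::rtree(max(2, params$n_genomes),
                       tip.label = if (params$n_genomes >= 2) genome_ids
                       else c(genome_ids, "outgroup"))
    truth <- structure(
      list(genes = dplyr::bind_rows(truth_genes),
           orthogroups = dplyr::bind_rows(truth_og),
           atranorin_clusters = atr_clusters,
           tree_newick = ape::write.tree(tree)),
      class = "truth_bundle"
    )
    list(genomes = genomes, truth = truth)
  })
}

#' Write a synthetic bundle to disk
#'
#' One sub-directory per genome (`proteins.faa`, `genes.gff3`,
#' `clusters.tsv`), plus `truth.json` and `tree.nwk` at the top level.
#'
#' @param bundle Output of [gen_genomes()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in bundle$genomes) {
    write_annotation(g, file.path(dir, g$genome))
  }
  truth <- bundle$truth
  jsonlite::write_json(
    list(genes = truth$genes, orthogroups = truth$orthogroups,
         atranorin_clusters = truth$atranorin_clusters),
    file.path(dir, "truth.json")
  )
  writeLines(truth$tree_newick, file.path(dir, "tree.nwk"))
  invisible(dir)
}

#' Simulate an amino-acid alignment on a known tree
#'
#' Root states are drawn from the model's stationary frequencies and child
#' states from the transition probabilities along each branch; columns are
#' independent sites (no indels, so the alignment is gap-free). With
#' discrete-gamma models each site first draws its rate category.
#'
#' @param tree An [ape::phylo] with >= 2 leaves and non-negative branch
#'   lengths.
#' @param model A [subst_model()].
#' @param length Number of sites (> 0).
#' @param seed Integer seed.
#' @return An `aa_alignment` with one row per leaf.
#' @export
gen_alignment <- function(tree, model, length, seed = 1) {
  if (length(tree$tip.label) < 2) abort("tree needs at least 2 leaves")
  if (is.null(tree$edge.length) || any(tree$edge.length < 0)) {
    abort("tree needs non-negative branch lengths")
  }
  if (length <= 0) abort("alignment length must be positive")
  withr::with_seed(derive_seed(seed, "alignment"), {
    ntip <- length(tree$tip.label)
    nnode <- ntip + tree$Nnode
    root <- ntip + 1L
    states <- matrix(NA_integer_, nnode, length)
    states[root, ] <- sample.int(20, length, replace = TRUE,
                                 prob = model$freqs)
    rates <- if (length(model$rates) > 1) {
      model$rates[sample.int(length(model$rates), length, replace = TRUE)]
    } else rep(1, length)
    tree_pre <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(tree_pre$edge))) {
      parent <- tree_pre$edge[e, 1]
      child <- tree_pre$edge[e, 2]
      t_edge <- tree_pre$edge.length[e]
      if (length(model$rates) > 1) {
        # per-site rates need per-site transition draws, grouped by rate
        child_states <- integer(length)
        for (r in unique(rates)) {
          P <- transition_prob(model, t_edge, r)
          idx <- which(rates == r)
          ps <- states[parent, idx]
          for (s in unique(ps)) {
            sel <- idx[ps == s]
            child_states[sel] <- sample.int(20, length(sel), replace = TRUE,
                                            prob = P[s, ])
          }
        }
      } else {
        P <- transition_prob(model, t_edge, 1)
        child_states <- integer(length)
        ps <- states[parent, ]
        for (s in unique(ps)) {
          sel <- which(ps == s)
          child_states[sel] <- sample.int(20, length(sel), replace = TRUE,
                                          prob = P[s, ])
        }
      }
      states[child, ] <- child_states
    }
    m <- matrix(model$states[states[seq_len(ntip), , drop = FALSE]],
                nrow = ntip)
    rownames(m) <- tree$tip.label
    aa_alignment(m)
  })
}
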