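# Genome censuses, aggregates, atranorin screen, cluster comparison.

test_that("census counts planted clusters by construction", {
  bundle <- gen_genomes(sim_params(n_genomes = 2, mean_clusters_per_genome = 3,
                                   seed = 101))
  g <- bundle$genomes[[1]]
  truth <- bundle$truth$genes[bundle$truth$genes$genome == g$genome, ]
  cen <- census_genome(g)
  expect_equal(cen$t1_total, nrow(truth))
  reg <- pks_group_registry()
  classes <- reg$class[match(truth$group, reg$name)]
  expect_equal(cen$nr, sum(classes == "NR"))
  expect_equal(cen$r, sum(classes == "R"))
  expect_equal(cen$clusters, nrow(g$clusters))
})

test_that("census of an empty genome is all zeros", {
  empty <- genome_annotation(
    genome = "void",
    genes = tibble::tibble(gene_id = character(), contig = character(),
                           start = integer(), end = integer(),
                           strand = character(), pfam = character(),
                           domains = character(), product = character(),
                           cluster_id = character()),
    clusters = tibble::tibble(cluster_id = character(),
                              type_label = character(),
                              core_gene_ids = character()),
    proteome = character()
  )
  cen <- census_genome(empty, classifications = tibble::tibble(
    gene_id = character(), reduction = character()))
  expect_equal(unlist(cen[, -1], use.names = FALSE), rep(0L, 7))
})

test_that("unclassified T1PKS cores are an error", {
  bundle <- gen_genomes(sim_params(n_genomes = 1, seed = 103))
  expect_error(
    census_genome(bundle$genomes[[1]],
                  classifications = tibble::tibble(gene_id = character(),
                                                   reduction = character())),
    "without classification"
  )
})

test_that("aggregates reproduce the published census summaries", {
  agg <- aggregate_census(census_fixture())
  expect_equal(agg$total_t1, 478)
  expect_equal(agg$pct_nr, 44.35)
  expect_equal(agg$pct_r, 53.35)
  expect_equal(agg$pct_pr, 2.3)
  expect_equal(agg$mean_clusters, 48L)
  expect_equal(agg$min_clusters, 26)
  expect_equal(agg$min_clusters_genome, "laspuspred")
  expect_equal(agg$max_clusters, 86)
  expect_equal(agg$max_clusters_genome, "eveprupred")
  expect_equal(agg$max_t1, 36)
  expect_equal(agg$max_t1_genome, "eveprupred")
  expect_false(agg$ties)
  # single row: aggregates echo that row
  one <- census_fixture()[3, ]
  agg1 <- aggregate_census(one)
  expect_equal(agg1$total_t1, one$t1_total)
  expect_equal(agg1$mean_clusters, as.integer(one$clusters))
  # zero TI-PKS: percentages undefined
  zero <- one
  zero$t1_total <- 0L; zero$nr <- 0L; zero$r <- 0L; zero$pr <- 0L
  expect_true(is.na(aggregate_census(zero)$pct_nr))
})

test_that("glance on a census table returns the aggregate", {
  expect_equal(glance(census_fixture()), aggregate_census(census_fixture()))
})

test_that("atranorin screen flags exactly the planted cluster", {
  bundle <- gen_genomes(sim_params(n_genomes = 2, plant_atranorin_in = 1,
                                   seed = 107))
  res <- dplyr::bind_rows(lapply(bundle$genomes, screen_atranorin_genome))
  expect_equal(res$cluster_id[res$verdict], bundle$truth$atranorin_clusters)
})

test_that("removing any accessory or failing the core flips the verdict", {
  bundle <- gen_genomes(sim_params(n_genomes = 1, plant_atranorin_in = 1,
                                   seed = 109))
  g <- bundle$genomes[[1]]
  cid <- bundle$truth$atranorin_clusters
  bgc <- get_bgc(g, cid)
  expect_true(screen_atranorin(bgc)$verdict)

  drop_gene <- function(bgc, pfam) {
    keep <- is.na(bgc$genes$pfam) | !grepl(pfam, bgc$genes$pfam, fixed = TRUE)
    bgc$genes <- bgc$genes[keep, ]
    bgc
  }
  for (pf in c("PF00067", "PF08241", "PF07690")) {
    v <- screen_atranorin(drop_gene(bgc, pf))
    expect_false(v$verdict, label = sprintf("dropped %s", pf))
  }
  v <- screen_atranorin(drop_gene(bgc, "PF00067"))
  expect_false(v$has_p450)

  # a core below the identity threshold fails even with all accessories
  strict <- screen_params(min_identity = 99, min_coverage = 50)
  expect_false(screen_atranorin(bgc, params = strict)$verdict)
})

test_that("transporter pfam policy switches the accepted accessions", {
  expect_setequal(transporter_pfams("either"), c("PF07690", "PF00400"))
  expect_equal(transporter_pfams("PF00400"), "PF00400")
  bundle <- gen_genomes(sim_params(n_genomes = 1, plant_atranorin_in = 1,
                                   seed = 113))
  bgc <- get_bgc(bundle$genomes[[1]], bundle$truth$atranorin_clusters)
  # the synthetic transporter is MFS (PF07690): the WD-40-only policy
  # must reject it, the default accepts it
  expect_true(screen_atranorin(bgc, pfam_policy = "either")$verdict)
  expect_true(screen_atranorin(bgc, pfam_policy = "PF07690")$verdict)
  expect_false(screen_atranorin(bgc, pfam_policy = "PF00400")$verdict)
})

test_that("a cluster compared with itself matches every gene at 100%", {
  bundle <- gen_genomes(sim_params(n_genomes = 1, plant_atranorin_in = 1,
                                   seed = 127))
  bgc <- get_bgc(bundle$genomes[[1]], bundle$truth$atranorin_clusters)
  cmp <- compare_clusters(bgc, bgc)
  matched <- cmp[!is.na(cmp$gene_a) & !is.na(cmp$gene_b), ]
  expect_equal(matched$gene_a, matched$gene_b)
  expect_true(all(matched$identity == 100))
  expect_equal(nrow(matched), nrow(bgc$genes))
})

test_that("planted atranorin clusters in two genomes match mutually", {
  bundle <- gen_genomes(sim_params(n_genomes = 2,
                                   plant_atranorin_in = c(1, 2), seed = 131))
  cids <- bundle$truth$atranorin_clusters
  a <- get_bgc(bundle$genomes[[1]], cids[1])
  b <- get_bgc(bundle$genomes[[2]], cids[2])
  cmp <- compare_clusters(a, b)
  # the two cores descend from the same reference: they must pair up
  core_row <- cmp[!is.na(cmp$gene_a) & cmp$gene_a == a$core_gene_ids[1], ]
  expect_equal(core_row$gene_b, b$core_gene_ids[1])
  expect_gte(core_row$identity, 30)
  # symmetry: swapping the clusters transposes the match set
  rev <- compare_clusters(b, a)
  fwd_pairs <- stats::na.omit(paste(cmp$gene_a, cmp$gene_b))
  rev_pairs <- stats::na.omit(paste(rev$gene_b, rev$gene_a))
  m1 <- cmp[!is.na(cmp$gene_a) & !is.na(cmp$gene_b), c("gene_a", "gene_b")]
  m2 <- rev[!is.na(rev$gene_a) & !is.na(rev$gene_b), c("gene_b", "gene_a")]
  expect_setequal(paste(m1$gene_a, m1$gene_b), paste(m2$gene_b, m2$gene_a))
})

test_that("clusters with disjoint gene families share no matches", {
  withr::with_seed(137, {
    mk <- function(prefix) {
      genes <- tibble::tibble(
        gene_id = paste0(prefix, 1:3), contig = "c",
        start = c(1L, 500L, 1000L), end = c(400L, 900L, 1400L),
        strand = "+", pfam = NA_character_, domains = NA_character_,
        product = "x", cluster_id = paste0(prefix, "_c")
      )
      proteins <- setNames(vapply(1:3, function(i) random_aa_seq(80), ""),
                           genes$gene_id)
      structure(list(id = paste0(prefix, "_c"), genome = prefix,
                     type_label = "T1PKS", genes = genes,
                     core_gene_ids = genes$gene_id[1], proteins = proteins),
                class = "bgc")
    }
    a <- mk("left")
    b <- mk("right")
  })
  cmp <- compare_clusters(a, b)
  matched <- cmp[!is.na(cmp$gene_a) & !is.na(cmp$gene_b), ]
  # unrelated random proteins may share spurious short hits, but none at
  # screening-grade identity+coverage
  if (nrow(matched) > 0) {
    expect_true(all(matched$identity < 100))
  }
  expect_true(all(c(a$genes$gene_id, b$genes$gene_id) %in%
                    c(cmp$gene_a, cmp$gene_b)))
})

test_that("census and comparison plots build without error", {
  p1 <- plot_census(census_fixture())
  expect_s3_class(p1, "ggplot")
  bundle <- gen_genomes(sim_params(n_genomes = 1, plant_atranorin_in = 1,
                                   seed = 139))
  bgc <- get_bgc(bundle$genomes[[1]], bundle$truth$atranorin_clusters)
  p2 <- plot_gene_arrows(compare_clusters(bgc, bgc))
  expect_s3_class(p2, "ggplot")
})
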