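>PKS23_synthetic_reference synthetic stand-in for an atranorin-cluster core PKS
CECHVHSPKNCWTAHGGIGQFHYLCSMRMYGNCRRGFSPIHCMLKEQFIRADDPFVDRMS
VYSADWHNYEDLETHYLMSDCARVYYEDHKNYVIIFVRQVNQKMNYYMHFSVCKVNKVKR
APMVVTNTQMYTGQHEYEHVQDLSGRIEYQYVDRYECMSSITPKKACQKSPTDCQIFIWH
YFWLGEAYIPELNGYGSPMDHAEAKLQHKPFQKLAFKDFTYIEWSHDEECFQGRTVGNEY
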