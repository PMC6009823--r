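# Default primer pairs and spike stock calibrations for the three amplicon
# families. Windows are full-amplicon (primer-inclusive) lengths in bp.
# Stocks are measured molecule counts per ng of delivered construct DNA.
P:
  name: "P/16S"
  forward: "GTGYCAGCMGCCGCGGTAA"        # 515F
  reverse: "GGACTACNVGGGTWTCTAAT"       # 806R
  amplicon_length_target: 253
  amplicon_length_window: [252, 254]
  stock_copies_per_ng: 3.7e8
  construct_length_bp: 2504
E:
  name: "E/18S"
  forward: "TCTGTGATGCCCTTAGATGTTCTGGG" # F1427
  reverse: "GCGGTGTGTACAAAGGGCAGGG"     # R1616
  amplicon_length_target: 211
  amplicon_length_window: [210, 212]
  stock_copies_per_ng: 3.8e8
  construct_length_bp: 2504
F:
  name: "F/ITS"
  forward: "CTTGGTCATTTAGAGGAAGTAA"     # ITS1F
  reverse: "GCTGCGTTCTTCATCGATGC"       # ITS2
  amplicon_length_target: 272
  amplicon_length_window: [250, 300]
  stock_copies_per_ng: 3.7e8
  construct_length_bp: 2504
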