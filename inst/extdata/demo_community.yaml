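# Small demo community for `iha simulate` / `iha run`: three genomes with
# a skewed abundance profile, one long repeat element and one plasmid.
divergence: 0.04
library:
  n_markers: 20
  marker_len: 300
genomes:
  - name: dom1
    length: 120000
    gc: 0.62
    abundance: 70
    circular: true
  - name: mid1
    length: 100000
    gc: 0.48
    abundance: 25
    circular: true
    repeats:
      - [2100, 4]
    plasmids:
      - [8000, 3]
  - name: rare1
    length: 80000
    gc: 0.34
    abundance: 5
    circular: true
reads:
  sr_bp: 3.0e+7
  sr_error: 0
  lr_bp: 1.0e+7
  lr_n50: 15000
  lr_error: 0.02
iha:
  cycle1_sr_bp: 6.0e+6
  cycle1_lr_bp: 2.2e+6
  later_sr_pairs: 20000
  later_lr_reads: 1000
  max_cycles: 4
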