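version: 1
# The three shipped screening protocols. They differ only in which BHS
# totals end screening before the BDI-9 stage; BHS >= 6 always refers
# immediately to a psychiatrist.
protocols:
  P1:   # original algorithm: BHS 0-1 stops, BDI-9 for 2-5
    bhs_stop_max: 1
    bhs_refer_min: 6
    bdi_assess_lo: 19
    bdi_assess_hi: 24
    bdi_refer_min: 25
  P2:   # variant: BHS 0-2 stops, BDI-9 for 3-5
    bhs_stop_max: 2
    bhs_refer_min: 6
    bdi_assess_lo: 19
    bdi_assess_hi: 24
    bdi_refer_min: 25
  P3:   # variant: BHS 0-3 stops, BDI-9 for 4-5
    bhs_stop_max: 3
    bhs_refer_min: 6
    bdi_assess_lo: 19
    bdi_assess_hi: 24
    bdi_refer_min: 25
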