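# Synthetic/reconstructed germline-transmission count table.
# Class counts are reconstructions: round(percentage * n) from the
# published disruption percentages (98.2% n=164; 92% and 97%, n not
# published, set to 200; 87.2% n=413). The QF2+ share among disrupted
# offspring was not published; for donor-carrying crosses it is set
# near the somatic HDR scale (~5% of disrupted). Only the disruption
# percentages are data; everything else is a modelling choice.
cross_id,GAL4plus,dGAL4,QF2plus
cas9_and_grna,3,153,8
cas9_only,16,184,0
grna_only,6,184,10
no_components,53,360,0
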