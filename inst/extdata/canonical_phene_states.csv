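phene_state,ccfn,ccs,respiration,optimum_n,minimum_n,diameter
reduced_ccfn,6,360,0.014,966.1,515.38,0.69
increased_ccfn,18,360,0.044,1141.02,816.66,1.62
large_ccs,10,450,0.012,989.49,591.46,1.07
small_ccs,10,200,0.046,1086.48,659.09,0.88
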