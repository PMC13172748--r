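group,v_std_cc,v_ref_cc,v_i_cc,ev_std_cc,ev_ref_cc,jc_ev,dsc_ev,jc,dsc
uniform_expansion,19.4,43.7,19.4,19.4,28.25,0.687,0.814,0.444,0.615
displaced_reference,19.4,43.7,19.4,19.4,31.19,0.622,0.767,0.444,0.615
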