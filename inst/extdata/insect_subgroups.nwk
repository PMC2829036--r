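(Crustacea,(Apterygota,(Paleoptera,(Polyneoptera,((Psocodea,Heteroptera),(Hymenoptera,((Coleoptera,Neuropterida),((Trichoptera,Lepidoptera),(Mecoptera,Diptera)))))))));
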