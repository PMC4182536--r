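res_class,region,phi_min,phi_max,psi_min,psi_max
general,core,-180,-30,-70,50
general,core,-180,-45,90,180
general,core,-180,-45,-180,-150
general,allowed,-180,-20,-110,80
general,allowed,-180,-20,80,180
general,allowed,-180,-20,-180,-140
general,allowed,30,90,-30,90
general,generous,-180,-10,-180,180
general,generous,20,120,-90,150
gly,core,-180,-30,-70,50
gly,core,-180,-45,90,180
gly,core,-180,-45,-180,-150
gly,core,20,180,-70,70
gly,allowed,-180,180,-180,180
pro,core,-110,-40,-60,30
pro,core,-110,-40,110,180
pro,allowed,-130,-30,-75,60
pro,allowed,-130,-30,60,180
pro,allowed,-130,-30,-180,-160
pro,generous,-180,-20,-180,180
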