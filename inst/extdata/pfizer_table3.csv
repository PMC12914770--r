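label,nc,xc,sc,nv,xv,sv,D
Overall March 2021,20713,850,6003,20712,77,6247,0.55
Overall Nov. 2020,17511,162,2222,17411,8,2214,0.21
Male,8762,81,1108,8875,3,1124,0.21
Hispanic or Latinx,4746,53,600,4764,3,605,0.21
Over 65,3880,19,511,3848,1,508,0.21
Brazil,1121,8,117,1129,1,119,0.21
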