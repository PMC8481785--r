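study,group,phase,mean_mmHg,sd_mmHg,n
Opherk,dcm,ED,18.6,11.4,12
Kass,dcm,ED,24.8,7.8,18
Hayashida,dcm,ED,14.0,10.0,17
Nagueh,hcm,ED,23.0,6.0,35
Nishimura-a,hcm,ED,25.0,9.0,54
Romeo,dcm,ES,120.0,20.0,69
Nishimura-a,hcm,ES,183.0,42.0,54
Nishimura-b,hcm,ES,196.0,43.0,21
Nishimura-b,hcm,ES,150.0,29.0,8
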