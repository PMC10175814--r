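region_class,attribute,category,count,n_nodules
hot,localization,on margin,27,100
hot,localization,not on margin,73,100
hot,echogenicity,very hypoechoic,84,100
hot,echogenicity,hypoechoic,16,100
hot,echogenicity,isoechoic,0,100
hot,composition,solid,100,100
hot,foci,macro-calcification,0,100
hot,foci,punctate calcification,40,100
hot,foci,none,60,100
inactivated,localization,on margin,93,100
inactivated,localization,not on margin,7,100
inactivated,echogenicity,very hypoechoic,43,100
inactivated,echogenicity,hypoechoic,52,100
inactivated,echogenicity,isoechoic,5,100
inactivated,composition,solid,100,100
inactivated,foci,macro-calcification,16,100
inactivated,foci,punctate calcification,14,100
inactivated,foci,none,70,100
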