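cohort,sample,experiment,mean_au,reference_cv_percent,reference_rank
standard_settings,Control 2,1,929,13,1
standard_settings,Control 2,2,768,13,1
standard_settings,BMD 1,1,415,9,2
standard_settings,BMD 1,2,367,9,3
standard_settings,BMD 3,1,387,4,3
standard_settings,BMD 3,2,412,4,2
standard_settings,BMD 4,1,359,7,4
standard_settings,BMD 4,2,323,7,4
standard_settings,BMD 2,1,200,4,5
standard_settings,BMD 2,2,213,4,5
standard_settings,DMD 1,1,58,24,6
standard_settings,DMD 1,2,82,24,6
standard_settings,DMD 2,1,44,43,7
standard_settings,DMD 2,2,82,43,7
high_laser,DMD 3,3,255,10,4
high_laser,DMD 3,4,241,10,4
high_laser,DMD 3,7,208,10,4
high_laser,DMD 1,3,286,14,3
high_laser,DMD 1,4,298,14,3
high_laser,DMD 1,7,228,14,3
high_laser,DMD 4,5,306,17,2
high_laser,DMD 4,6,427,17,2
high_laser,DMD 4,7,354,17,2
high_laser,DMD 5,5,406,2,1
high_laser,DMD 5,7,397,2,1
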