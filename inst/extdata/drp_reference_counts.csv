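pair,donor_type,n_nssnp,smm_presented,smm_strong,pan_presented,pan_strong,shared_presented
2,MRD,4446,1926,250,3883,1376,1332
4,MRD,4448,5412,825,3962,885,2441
16,MRD,3290,2111,177,1071,427,417
23,MRD,3657,13456,705,787,118,534
3,URD,7227,72294,21339,7242,2509,4881
5,URD,6572,30730,2254,2759,538,1865
7,URD,6725,58209,21548,5231,2178,2931
8,URD,6573,65298,19275,4831,2000,2445
10,URD,9203,18396,2283,5002,989,2065
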