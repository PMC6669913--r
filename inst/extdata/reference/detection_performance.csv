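"analysis","subject","n_commands","correct","total","accuracy_pct","itr_bits_min","flagged"
"offline_candidates",1,5,8,15,53.3,0.52,FALSE
"offline_candidates",2,5,10,15,66.7,0.98,FALSE
"offline_candidates",3,5,8,15,53.3,0.52,FALSE
"offline_candidates",4,5,10,15,66.7,0.98,FALSE
"offline_candidates",5,5,11,15,73.3,1.27,FALSE
"offline_candidates",6,5,9,15,60,0.73,FALSE
"offline_candidates",7,5,15,15,100,3.1,FALSE
"offline_candidates",8,5,10,15,66.7,0.98,FALSE
"offline_candidates",9,5,9,15,60,0.73,FALSE
"offline_candidates",10,5,15,15,100,3.1,FALSE
"offline_candidates",1,4,27,60,45,0.18,FALSE
"offline_candidates",2,4,38,60,63.3,0.63,FALSE
"offline_candidates",3,4,35,60,58.3,0.48,FALSE
"offline_candidates",4,4,38,60,63.3,0.63,FALSE
"offline_candidates",5,4,47,60,78.3,1.2,FALSE
"offline_candidates",6,4,35,60,58.3,0.48,FALSE
"offline_candidates",7,4,58,60,96.67,2.32,FALSE
"offline_candidates",8,4,39,60,65,0.68,FALSE
"offline_candidates",9,4,39,60,65,0.68,FALSE
"offline_candidates",10,4,57,60,95,2.18,FALSE
"offline_candidates",1,3,46,90,51.1,0.13,FALSE
"offline_candidates",2,3,60,90,66.7,0.44,FALSE
"offline_candidates",3,3,55,90,61.1,0.31,FALSE
"offline_candidates",4,3,61,90,67.8,0.47,FALSE
"offline_candidates",5,3,72,90,80,0.88,FALSE
"offline_candidates",6,3,53,90,58.9,0.26,FALSE
"offline_candidates",7,3,90,90,100,2.11,FALSE
"offline_candidates",8,3,57,90,63.3,0.36,FALSE
"offline_candidates",9,3,58,90,64.4,0.39,FALSE
"offline_candidates",10,3,86,90,95.6,1.7,FALSE
"offline_candidates",1,2,40,60,66.7,0.11,FALSE
"offline_candidates",2,2,42,60,70,0.16,FALSE
"offline_candidates",3,2,43,60,71.7,0.19,FALSE
"offline_candidates",4,2,45,60,75,0.25,FALSE
"offline_candidates",5,2,51,60,85,0.52,FALSE
"offline_candidates",6,2,43,60,71.7,0.19,FALSE
"offline_candidates",7,2,60,60,100,1.33,FALSE
"offline_candidates",8,2,43,60,71.7,0.19,FALSE
"offline_candidates",9,2,51,60,85,0.52,FALSE
"offline_candidates",10,2,56,60,93.3,0.86,FALSE
"offline_all",1,4,36,60,60,0.53,FALSE
"offline_all",2,4,42,60,70,0.86,FALSE
"offline_all",3,4,36,60,60,0.53,FALSE
"offline_all",4,4,42,60,70,0.86,FALSE
"offline_all",5,4,47,60,78.3,1.2,FALSE
"offline_all",6,4,37,60,61.7,0.58,FALSE
"offline_all",7,4,60,60,100,2.67,FALSE
"offline_all",8,4,43,60,71.7,0.92,FALSE
"offline_all",9,4,40,60,66.7,0.74,FALSE
"offline_all",10,4,60,60,100,2.67,FALSE
"offline_all",1,3,60,90,66.7,0.44,FALSE
"offline_all",2,3,67,90,74.4,0.68,FALSE
"offline_all",3,3,61,90,67.8,0.47,FALSE
"offline_all",4,3,68,90,75.6,0.72,FALSE
"offline_all",5,3,76,90,84.4,1.07,FALSE
"offline_all",6,3,60,90,66.7,0.44,FALSE
"offline_all",7,3,90,90,100,2.11,FALSE
"offline_all",8,3,69,90,76.7,0.76,FALSE
"offline_all",9,3,67,90,74.4,0.68,FALSE
"offline_all",10,3,90,90,100,2.11,FALSE
"offline_all",1,2,45,60,75,0.25,FALSE
"offline_all",2,2,50,60,83.3,0.47,FALSE
"offline_all",3,2,47,60,78.3,0.33,FALSE
"offline_all",4,2,50,60,83.3,0.47,FALSE
"offline_all",5,2,55,60,91.7,0.78,FALSE
"offline_all",6,2,45,60,75,0.25,FALSE
"offline_all",7,2,60,60,100,1.3,TRUE
"offline_all",8,2,51,60,85,0.52,FALSE
"offline_all",9,2,51,60,85,0.52,FALSE
"offline_all",10,2,60,60,100,1.3,TRUE
"online1",1,3,5,6,83.3,1.02,FALSE
"online1",2,3,3,6,50,0.11,FALSE
"online1",3,3,4,6,66.7,0.44,FALSE
"online1",4,3,6,6,100,2.11,FALSE
"online1",5,3,6,6,100,2.11,FALSE
"online1",6,3,6,6,100,2.11,FALSE
"online1",7,3,6,6,100,2.11,FALSE
"online1",8,3,4,6,66.7,0.44,FALSE
"online1",9,3,3,6,50,0.11,FALSE
"online1",10,3,5,6,83.3,1.02,FALSE
"online2",1,3,16,24,66.7,0.44,FALSE
"online2",2,3,16,24,66.7,0.44,FALSE
"online2",3,3,9,24,37.5,0.01,FALSE
"online2",4,3,15,24,62.5,0.34,FALSE
"online2",5,3,19,24,79.2,0.85,FALSE
"online2",6,3,13,24,54.2,0.18,FALSE
"online2",7,3,11,24,45.8,0.06,FALSE
"online2",8,3,13,24,54.2,0.18,FALSE
"online2",9,3,17,24,70.8,0.56,FALSE
"online2",10,3,21,24,87.5,1.22,FALSE
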