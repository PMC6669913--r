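"analysis","true","predicted","count"
"offline",1,1,17
"offline",1,2,5
"offline",1,3,5
"offline",1,4,1
"offline",1,5,2
"offline",2,1,2
"offline",2,2,24
"offline",2,3,1
"offline",2,4,1
"offline",2,5,2
"offline",3,1,2
"offline",3,2,2
"offline",3,3,22
"offline",3,4,1
"offline",3,5,3
"offline",4,1,6
"offline",4,2,2
"offline",4,3,3
"offline",4,4,18
"offline",4,5,1
"offline",5,1,0
"offline",5,2,3
"offline",5,3,2
"offline",5,4,1
"offline",5,5,24
"online1",1,1,18
"online1",1,3,1
"online1",1,5,1
"online1",3,1,3
"online1",3,3,13
"online1",3,5,4
"online1",5,1,1
"online1",5,3,2
"online1",5,5,17
"online2",1,1,50
"online2",1,3,13
"online2",1,5,17
"online2",3,1,19
"online2",3,3,47
"online2",3,5,14
"online2",5,1,18
"online2",5,3,9
"online2",5,5,53
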