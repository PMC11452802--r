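"video_id","second_index","probability"
"vidA",0,0.9
"vidA",1,0.9
"vidA",2,0.9
"vidA",3,0.1
"vidA",4,0.1
"vidA",5,0.1
"vidA",6,0.1
"vidA",7,0.1
"vidA",8,0.1
"vidA",9,0.1
"vidB",0,0.8
"vidB",1,0.8
"vidB",2,0.8
"vidB",3,0.2
"vidB",4,0.8
"vidB",5,0.8
"vidB",6,0.2
"vidB",7,0.8
"vidB",8,0.8
"vidB",9,0.8
"vidB",10,0.8
"vidB",11,0.2
"vidC",0,0.2
"vidC",1,0.2
"vidC",2,0.2
"vidC",3,0.2
"vidC",4,0.2
"vidC",5,0.2
"vidC",6,0.2
"vidC",7,0.2
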