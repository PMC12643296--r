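ffg,Pond 1,Pond 2,Pond 3,Ditch 1,Ditch 2,Ditch 3,Ditch 4
collector_filterer,0,0,0,3,0,0,9
collector_gatherer,13,5,3,11,10,10,10
grazer_scraper,37,8,11,16,14,18,16
omnivore,15,31,22,28,23,30,25
predator,19,19,14,38,45,26,60
shredder,24,7,0,18,21,10,12
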