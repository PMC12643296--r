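site_id,wb_type,temp,ec,ph,o2,nh4,no3,no2,po4,tu_algae,tu_invertebrate,n_habitats,n_detections
Pond 1,pond,7.4,1570,6.2,5.2,0.01,0.20,0,0.25,-2.686,-5.221,3,3
Pond 2,pond,10.5,1112,6.5,10.6,0.09,0.14,0,0.05,-4.057,-5.074,2,1
Pond 3,pond,11.2,881,7.0,13.8,0.08,0.23,0,0.11,-2.650,-4.632,3,4
Ditch 1,ditch,9.7,588,7.0,11.5,0.86,1.10,0,0.44,-2.685,-5.428,2,4
Ditch 2,ditch,8.3,815,7.6,6.1,0.08,0.72,0,0.06,-3.253,-5.116,1,6
Ditch 3,ditch,11.0,928,7.0,8.8,0.08,0.36,0,0.06,-2.614,-4.817,3,7
Ditch 4,ditch,12.7,900,8.0,8.8,0.08,1.32,0,0.03,-3.456,-4.925,2,7
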