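site,iso_year,start_week,egg_count
Reichstett,2019,20,16
Reichstett,2019,22,921
Reichstett,2019,24,3525
Reichstett,2019,26,3994
Reichstett,2019,28,2466
Reichstett,2019,30,4339
Reichstett,2019,32,2338
Reichstett,2019,34,2412
Reichstett,2019,36,1112
Reichstett,2019,38,791
Reichstett,2019,40,2448
Reichstett,2019,42,1336
Reichstett,2019,44,60
Reichstett,2019,46,51
Reichstett,2020,20,529
Reichstett,2020,22,1592
Reichstett,2020,24,1243
Reichstett,2020,26,1489
Reichstett,2020,28,1698
Reichstett,2020,30,3491
Reichstett,2020,32,2136
Reichstett,2020,34,1338
Reichstett,2020,36,876
Reichstett,2020,38,172
Reichstett,2020,40,1992
Reichstett,2020,42,200
Reichstett,2020,44,103
Bas-Rhin,2019,21,395
Bas-Rhin,2019,23,395
Bas-Rhin,2019,25,858
Bas-Rhin,2019,27,247
Bas-Rhin,2019,29,943
Bas-Rhin,2019,31,833
Bas-Rhin,2019,33,1078
Bas-Rhin,2019,35,382
Bas-Rhin,2019,37,19
Bas-Rhin,2019,39,34
Bas-Rhin,2019,41,152
Bas-Rhin,2019,43,215
Bas-Rhin,2020,25,306
Bas-Rhin,2020,27,680
Bas-Rhin,2020,29,2604
Bas-Rhin,2020,31,1512
Bas-Rhin,2020,33,1073
Bas-Rhin,2020,35,1499
Bas-Rhin,2020,37,487
Bas-Rhin,2020,39,228
Bas-Rhin,2020,41,221
Bas-Rhin,2020,43,0
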