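iso_year,iso_week,egg_count
2019,20,16
2019,22,921
2019,24,3525
2019,26,3994
2019,28,2466
2019,30,4339
2019,32,2338
2019,34,2412
2019,36,1112
2019,38,791
2019,40,2448
2019,42,1336
2019,44,60
2019,46,51
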