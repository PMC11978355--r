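y,x1,x2
8,6.454983618243815613,3.9848739002432310
27,8.873204679676939932,7.3897675498017934
14,8.867367798293230408,3.0642165999206639
91,3.633340649219344520,12.6022684371333700
22,9.258517630182891978,3.5633914655159420
11,0.044798307386105837,21.1216689532455000
127,2.209044087731275141,2.1721869634692359
113,4.460172518554792020,6.0835090091331212
31,4.343220416069559775,1.8809646970277190
142,0.550052711934619465,6.2608619025005110
59,0.208209676991126885,6.1959692864017457
119,2.021530197504858073,19.7273617217926827
198,0.443118553997625453,8.2826917764508714
114,2.724268405761314682,8.2764901922765350
61,3.254114171826635094,2.5418211480100403
170,10.679454340324218364,9.0164039980922972
31,0.727296823784659319,5.9089130262758180
879,0.056794379614979594,9.2473682014487313
26,0.055985626044755668,5.1564626945007914
514,0.012480435596469592,13.4452557097246306
18,5.577409822199313361,3.6436724007102739
47,1.519792150711815504,5.0323804471927733
14,6.104064834551605756,7.7135606301410053
21,2.354005678857227668,3.9731298198621321
47,7.804149380747853471,19.6978851536589410
52,9.215020588961204240,1.8090829818270926
38,4.705007968904427074,7.9326181969828378
30,5.737095954572624557,10.6305544995104189
43,11.916744430798251742,10.8478139327450194
394,4.140795108752265641,6.0461522245523645
235,3.274292048041227865,1.9317803827530138
291,1.916726116065548657,11.0024051442924442
70,2.421879341820699860,11.2138148429502262
57,0.202547770666586691,4.2200092166598075
58,4.119555518688068574,7.8220189331998338
363,6.520187428893322590,2.5454953083405547
70,10.716332500895576985,5.5390379667252372
47,4.736416623529282610,4.6899900046858072
14,4.934209255305319175,6.5098757789904296
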