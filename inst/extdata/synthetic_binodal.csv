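"w_dex_wt_pct","w_peg_wt_pct","tie_id"
0.1,30.1404837777105,NA
2.17916666666667,16.4475140015812,NA
4.25833333333333,12.0895565383205,NA
6.3375,9.50843070457374,NA
8.41666666666667,7.73402249157494,NA
10.4958333333333,6.41502662978264,NA
12.575,5.38422658668727,NA
14.6541666666667,4.5498583534685,NA
16.7333333333333,3.85697524307932,NA
18.8125,3.27071811843076,NA
20.8916666666667,2.76806016272842,NA
22.9708333333333,2.33332387809432,NA
25.05,1.95555668332573,NA
27.1291666666667,1.62689805426653,NA
29.2083333333333,1.3415130353602,NA
31.2875,1.09487098896006,NA
33.3666666666667,0.883249197152865,NA
35.4458333333333,0.703392963740882,NA
37.525,0.552291254869978,NA
39.6041666666667,0.42704114592601,NA
41.6833333333333,0.324781352022302,NA
43.7625,0.242678270432002,NA
45.8416666666667,0.177949315842751,NA
47.9208333333333,0.127909196274595,NA
50,0.0900259567820221,NA
4.15522299000229,12.2504594671127,1
21.7271347149026,2.58590801841909,1
2.77675055637772,14.8902887164789,2
26.8039707970779,1.67531758409689,2
1.61609913731942,18.3066755806153,3
33.2802541389817,0.891390329700954,3
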