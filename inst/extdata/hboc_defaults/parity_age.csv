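age_group,children,cdf
0-19,0,0.87944995
0-19,1,0.9916994
0-19,2,0.99961234
0-19,3,0.99998624
0-19,4,0.99999963
0-19,5,0.99999999
0-19,6,1
0-19,7,1
0-19,8,1
20-24,0,0.58954144
20-24,1,0.89021731
20-24,2,0.97941069
20-24,3,0.99695399
20-24,4,0.99964401
20-24,5,0.99996922
20-24,6,0.99999827
20-24,7,0.99999995
20-24,8,1
25-29,0,0.2785016
25-29,1,0.57665545
25-29,2,0.81705666
25-29,3,0.93422215
25-29,4,0.97959556
25-29,5,0.99474742
25-29,6,0.99900888
25-29,7,0.99989977
25-29,8,1
30-34,0,0.17378642
30-34,1,0.35786336
30-34,2,0.62090033
30-34,3,0.81082641
30-34,4,0.91525402
30-34,5,0.96560574
30-34,6,0.98791158
30-34,7,0.99701512
30-34,8,1
35-39,0,0.15310406
35-39,1,0.29162638
35-39,2,0.54447443
35-39,3,0.75183983
35-39,4,0.87790531
35-39,5,0.94469178
35-39,6,0.97737465
35-39,7,0.99168853
35-39,8,1
40-44,0,0.15020263
40-44,1,0.28077795
40-44,2,0.53097942
40-44,3,0.74080792
40-44,4,0.8705435
40-44,5,0.94032585
40-44,6,0.97516309
40-44,7,0.99012365
40-44,8,1
45+,0,0.15
45+,1,0.28
45+,2,0.53
45+,3,0.74
45+,4,0.87
45+,5,0.94
45+,6,0.975
45+,7,0.99
45+,8,1
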