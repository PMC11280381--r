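pIC50
5.879
6.106
6.827
6.578
6.082
7.125
7.260
7.018
5.770
5.979
6.654
6.449
5.785
7.066
6.842
6.924
5.863
6.629
5.457
7.009
5.487
6.684
6.790
5.678
5.553
5.319
5.585
5.357
6.046
6.357
6.000
5.824
5.886
5.538
5.886
5.658
5.770
5.658
5.620
5.398
5.638
5.387
5.432
6.143
6.959
6.230
6.071
6.208
5.921
6.149
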