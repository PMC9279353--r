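"pH","intensity"
5.6,19.56
5.7,24.5
5.8,30.65
5.9,38.29
6,47.73
6.1,59.35
6.2,73.59
6.3,90.91
6.4,111.82
6.5,136.81
6.6,166.34
6.7,200.76
6.8,240.25
6.9,284.75
7,333.86
7.1,386.86
7.2,442.69
7.3,500
7.4,557.31
7.5,613.14
7.6,666.14
7.7,715.25
7.8,759.75
7.9,799.24
8,833.66
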