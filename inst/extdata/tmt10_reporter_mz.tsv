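channel	mz
126	126.127726
127N	127.124761
127C	127.131081
128N	128.128116
128C	128.134436
129N	129.131471
129C	129.137790
130N	130.134825
130C	130.141145
131	131.138180
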