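resid,bw
67,1.60
75,2.40
78,2.43
134,3.49
135,3.50
243,6.36
307,7.56
304,7.53
309,8.48
310,8.49
311,8.50
69,IL1
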