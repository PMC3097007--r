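# Postcard arm of the deliberate self poisoning trial exactly as
# published. These counts sum to 150, which contradicts the stated arm
# size n = 145 and the published mean 0.20 (they give 0.233); the
# reconciled version in carter_men.tsv is used for analysis.
value	control	postcard
0	86	125
1	13	13
2	2	10
3	0	2
4	1	0
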