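name	mu_t	mu_s	beta
water	0.028	0.182	0.0769230769230769
cube1	0.028	0.182	0.0192307692307692
cube2	0.028	0.182	0.0384615384615385
cube3	0.028	0.182	0.1428571428571428
cube4	0.028	0.182	0.2857142857142857
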