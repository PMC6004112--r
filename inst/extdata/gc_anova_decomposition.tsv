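region	term	df	sum_sq
five_prime	GCref	1	4.518
five_prime	Dref	1	58.766
five_prime	Residuals	562	123.808
three_prime	GCref	1	37.999
three_prime	Dref	1	50.025
three_prime	Residuals	562	135.407
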