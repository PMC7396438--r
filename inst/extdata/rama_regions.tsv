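region	phi	psi
alpha	-160	-100
alpha	-20	-100
alpha	-20	60
alpha	-160	60
beta	-180	60
beta	-40	60
beta	-40	240
beta	-180	240
left_alpha	20	-60
left_alpha	100	-60
left_alpha	100	100
left_alpha	20	100
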