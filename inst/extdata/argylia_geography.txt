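13	4	(A B C D)
uspallatensis	0100
bustillosii	0010
tomentosa	0100
bifrons	0100
glutinosa	0100
geranioides	0100
checoensis	0100
farnesiana	0100
robusta	0001
potentillifolia	0100
radiata	1010
adscendens_adscendens	0110
adscendens_viridis	0110
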