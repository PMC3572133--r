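name	value
atp_bind	0.9
adp_bind	4.5
adp_release_trail	12
p_release	250
step_fwd	7000
step_bwd	0.65
gating_g	1
atp_dissoc	0
p_bind	0
slip_fwd	5e-10
slip_bwd	5e-10
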