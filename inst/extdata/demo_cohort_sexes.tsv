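sample	group	sex
BAD002	Baden	M
S9	BkI	M
S1	BkII	M
S2	BkII	M
S4	BkII	M
S5	BkII	M
S6	BkII	M
S7	BkII	F
S8	BkII	M
S10	BkII	M
S11	BkII	M
S13	BkII	F
S45	BkII	M
S14	BkIII	F
S15	BkIII	M
S16	BkIII	M
S17	BkIII	M
S18	BkIII	M
S19	BkIII	M
S20	BkIII	M
S21	BkIII	F
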