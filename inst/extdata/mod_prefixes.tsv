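psimod_id	prefix	includes_coordinate	phospho
MOD:00046	p	TRUE	TRUE
MOD:00047	p	TRUE	TRUE
MOD:00048	p	TRUE	TRUE
MOD:00696	p	TRUE	TRUE
MOD:00115	PalmC	FALSE	FALSE
MOD:00068	MyrG	FALSE	FALSE
MOD:01148	Ub	TRUE	FALSE
MOD:00064	AcK	TRUE	FALSE
MOD:00084	Me2K	TRUE	FALSE
MOD:00083	Me3K	TRUE	FALSE
MOD:00414	MeR	TRUE	FALSE
MOD:00126	Btn	FALSE	FALSE
MOD:00110	GerC	FALSE	FALSE
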