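gomf_term	verb	template
biotin-protein ligase activity	biotinylates	catalyzes
esterase activity	hydrolyses	catalyzes
prostaglandin-D synthase activity	isomerizes	catalyzes
alpha-1,2-mannosyltransferase activity	transfers	transfers
glycylpeptide N-tetradecanoyltransferase activity	transfers	transfers
sodium:proton antiporter activity	exchanges	exchanges
sialic acid:proton symporter activity	cotransports	cotransports
GABA:sodium:chloride symporter activity	cotransports	cotransports
protein serine/threonine kinase activity	phosphorylates	catalyzes
protein tyrosine kinase activity	phosphorylates	catalyzes
fructokinase activity	phosphorylates	catalyzes
transmembrane transporter activity	transports	transports
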