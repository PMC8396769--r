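population	group	n	haplotype	frequency
southeast_br	control	597	TGG	0.28
southeast_br	control	597	GGA	0.09
southeast_br	control	597	GGG	0.04
southeast_br	control	597	GAA	0.52
southeast_br	case	777	TGG	0.36
southeast_br	case	777	GGA	0.07
southeast_br	case	777	GGG	0.08
southeast_br	case	777	GAA	0.40
afr_reference	panel	504	TGG	0.47
afr_reference	panel	504	GGA	0.32
afr_reference	panel	504	GGG	0.19
eur_reference	panel	503	TGG	0.27
eur_reference	panel	503	GGA	0.04
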