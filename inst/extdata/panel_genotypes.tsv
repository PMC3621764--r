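#positions:		20800461	20813939	21039041	21170872	21219342	21424689	21460798	21500736	21628290	21767668	21798425	21804207	21912348	21990579	21995335
individual	class	rs16101051	rs14754601	rs16761892	rs14754985	rs14755033	rs14755201	GGaluGA349261	rs14755269	rs16101716	rs16101791	rs14755437	GGaluGA349348	rs16762348	rs14755615	rs16102103
co-276F	mutant	A	T	G	G	A	A	G	A	A	A	T	C	A	A	A
overall	carrier	AA	GG	AA	AA	GG	CC	AA	GG	GG	GA	CT	CC	AA	AA	AA
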