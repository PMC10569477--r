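name	sequence	region_start	region_end	orientation	mix
Fw1_G1	TCTWACTCWTGGACSTATTCGG	112	133	fw	Fw1_mixA
Fw1_G2	ACTAWGTCTTCGACGAAWTCCG	112	133	fw	Fw1_mixA
Fw1_G3	ACAAAGTSTTCGACGAATTSCG	112	133	fw	Fw1_mixA;Fw1_mixB
Fw1_G4	TGTAASACTAGGTSGTTTTCGG	112	133	fw	Fw1_mixA;Fw1_mixB
Fw1_G5	TCAATCTGTTSGAGGTATACGC	112	133	fw	Fw1_mixA;Fw1_mixB
Fw1_G6	TGTAACTCATGGTCGWAATCCG	112	133	fw	Fw1_mixA;Fw1_mixB
Fw1_G7	ACTATCWCTAGGACCTATTGGC	112	133	fw	Fw1_mixA;Fw1_mixB
Fw1_G1n	TCTWACTCWTGSACSTATTCGG	112	133	fw	Fw1_mixB
Fw1_G2af	ACWAWGTCTTCGACGAAWTCCG	112	133	fw	Fw1_mixB
Rv1_G1	CCTCWGACACAWACTASCGTA	948	968	rv	Rv1
Rv1_G2	GSTGTGASAGATWCAAGSGAA	948	968	rv	Rv1
Rv1_G3	CCACTCACWCTTACTTGCSTT	948	968	rv	Rv1
Rv1_G4	GCTSTGTCASAAAGTWGCCTA	948	968	rv	Rv1
Rv1_G5	CGTCAGAGACWTTCTACCGAA	948	968	rv	Rv1
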