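Pocket 1 :
	Score : 	0.2133
	Druggability Score : 	0.049
	Number of Alpha Spheres : 	41
	Total SASA : 	718.99
	Polar SASA : 	301.45
	Apolar SASA : 	417.54
	Volume : 	824.31
	Mean local hydrophobic density : 	12.667
	Mean alpha sphere radius : 	3.741
	Mean alp. sph. solvent access : 	0.487
	Apolar alpha sphere proportion : 	0.366
	Hydrophobicity score:	18.400
	Volume score: 	 4.200
	Polarity score:	 8
	Charge score :	 1
	Proportion of polar atoms: 	42.105
	Alpha sphere density : 	5.312
	Cent. of mass - Alpha Sphere max dist: 	12.884
	Flexibility : 	0.329

Pocket 2 :
	Score : 	0.0981
	Druggability Score : 	0.018
	Number of Alpha Spheres : 	22
	Total SASA : 	245.56
	Polar SASA : 	104.88
	Apolar SASA : 	140.68
	Volume : 	310.77
	Mean local hydrophobic density : 	6.500
	Mean alpha sphere radius : 	3.622
	Mean alp. sph. solvent access : 	0.512
	Apolar alpha sphere proportion : 	0.318
	Hydrophobicity score:	11.250
	Volume score: 	 3.500
	Polarity score:	 5
	Charge score :	 0
	Proportion of polar atoms: 	45.455
	Alpha sphere density : 	4.107
	Cent. of mass - Alpha Sphere max dist: 	9.412
	Flexibility : 	0.281
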