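# MutPred2 pathogenicity scores with top mechanism hypotheses (description and
# p-value, semicolon-separated "description=p" pairs) and ModPred
# post-translational-modification predictions for the three shortlisted
# variants. MutPred2 score >= 0.5 = pathogenic; ModPred score < 0.7 low,
# >= 0.7 medium, >= 0.9 high confidence.
rsid	gene	aa_change	mutpred_score	features	modpred_ptm	modpred_score
rs10936600	LRRC34	L286I	0.55	Altered ordered interface=0.01;Altered metal binding=0.04	Proteolytic cleavage	0.07
rs757978	FARP2	T260N	0.70	Altered DNA binding=0.0028;Gain of allosteric site at F265=0.03;Altered disordered interface=0.04	Proteolytic cleavage	0.49
rs1126809	TYR	R402Q	0.74	Altered disordered interface=0.03;Loss of allosteric site at R403=0.0063;Altered DNA binding=0.0091;Altered transmembrane protein=0.0046	Proteolytic cleavage	0.58
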