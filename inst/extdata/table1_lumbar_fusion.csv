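outcome,treatment,p_best,sucra,p_score,comment
fusion_rate,Circumferential,0.999,1.000,0.999,
fusion_rate,MTLIF,0.000,0.363,0.336,
fusion_rate,PLF,0.000,0.264,0.252,
fusion_rate,PLIF,0.000,0.443,0.460,
fusion_rate,TLIF,0.000,0.359,0.357,
fusion_rate,XLIF,0.001,0.571,0.596,
ODI,MTLIF,0.327,0.366,0.327,p_best transcribed verbatim; ODI p_best column sums to 2.0 and duplicates p_score
ODI,PLF,0.714,0.738,0.714,p_best transcribed verbatim; ODI p_best column sums to 2.0 and duplicates p_score
ODI,PLIF,0.660,0.583,0.660,p_best transcribed verbatim; ODI p_best column sums to 2.0 and duplicates p_score
ODI,TLIF,0.299,0.312,0.299,p_best transcribed verbatim; ODI p_best column sums to 2.0 and duplicates p_score
adverse_event,Circumferential,0.120,0.505,0.548,
adverse_event,MTLIF,0.594,0.823,0.837,
adverse_event,PLF,0.061,0.500,0.536,
adverse_event,PLIF,0.027,0.361,0.307,
adverse_event,TLIF,0.026,0.377,0.375,
adverse_event,XLIF,0.172,0.434,0.396,
operative_time,MTLIF,0.058,0.298,0.306,
operative_time,PLF,0.500,0.771,0.804,
operative_time,PLIF,0.091,0.423,0.363,
operative_time,TLIF,0.114,0.519,0.507,
operative_time,XLIF,0.237,0.490,0.520,
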