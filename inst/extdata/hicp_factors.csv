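year,factor_to_2010
2004,1.097
2005,1.081
2006,1.063
2007,1.046
2008,1.023
2009,1.013
2010,1.000
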