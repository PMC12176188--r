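year,doctorates,revenue
2000,861,1.196
2001,830,1.176
2002,809,1.269
2003,867,1.240
2004,948,1.307
2005,1129,1.435
2006,1453,1.601
2007,1656,1.654
2008,1787,1.803
2009,1611,1.734
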