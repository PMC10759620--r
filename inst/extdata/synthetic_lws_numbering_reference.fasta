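>synthetic_LWS_numbering_reference length=364 (synthetic stand-in, not a real opsin)
MIRPWGYFPDSDRHSCSAAYRNRTMATVVMSLNIDSYWAPCMREEGNWETWCPNTTNVVW
WHRVQGVWTRSLCWGEHFVCVWTFLGNFVVWTDCMEQCTNGTIWQRANWEEMDPHWDAHK
HFMVRFLWPARHDLVVVAQCVSDNSIGHSYKFDAYEPKEWFCSYMNKMWVYCHGHLNDES
VVHRWPTWMNFHMGCAHGVKICCGTIQKWCLCCECQGWRMMSAQSDVAPQFKIFCHFDVW
TERYVHLFSQVWGSNRRLIWTSNMGTHKLFTLESWCYSSSPTQHTPWMDFKHYIYLEHNR
NTKANYNADKHELNNKTYSNELHCSFLWSNVCFCCHYQDAVHDRPMPEHAYKKINPPKPV
YMHG
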