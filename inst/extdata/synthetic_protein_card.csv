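"level","L","a","b"
"-",91.703,-20.1377,55.3475
"-+",88.2414,-4.1643,-17.9056
"+",84.945,-4.7666,-22.994
"++",79.1559,-6.2478,-32.0165
"+++",72.6906,-9.1319,-42.2228
"++++",69.1504,-7.6531,-47.83
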