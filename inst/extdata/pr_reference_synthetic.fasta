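>PR_ref_synthetic synthetic canonical-like proteorhodopsin reference (D97 T101 L105 E108)
SSSLNLEGGAIKITVVSLAVKGIGFFYWMVSFSHDGDSAYIAGSLAFYLEMAHTDDTVAVEAFWQAVDSK
TIPTQNTMALKALKTEELWTVTLVTIDYLATFQSLNAEFSVAAAAVAWQKFIATASLAAKNVGWYAQALM
SVRASWSPVGWSGDGLLGRLSTICLGRAQMADMVGALTLIPLQFGKGSVWTLNGIGTFPCTYVWLMIVSY
LWAVDAGPKVGYGDAAVAAEDSVDIGDIIGFLYTMAAWS
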