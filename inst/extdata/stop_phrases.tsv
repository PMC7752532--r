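# Stop phrases: longer phrases in which a cancer keyword loses its cancer
# meaning. Occurrences are masked in place before concept matching.
# phrase<TAB>note
agseong virus	computer virus ("agseong" = malignant)
an-am	Anam, a district in Seoul (contains "am" = cancer)
game	contains "am"; gaming context
drama	contains "am"; TV drama context
program	contains "am"; broadcast/software context
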