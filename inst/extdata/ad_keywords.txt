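# Advertising keywords: a post containing any of these (after normalization)
# is flagged as an advertisement and removed from analysis.
detoxification
antioxidant therapy
enzyme therapy
miracle cure
special discount
free consultation
order now
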