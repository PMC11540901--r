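# monitoring frequency by priority level; placeholder defaults, replace
# with local policy (the published model scales frequency with priority
# but does not print the values)
'1': monthly
'2': quarterly
'3': semi-annual
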