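sequence_id	position	alkyl_group
lesion12mer	6	Et
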