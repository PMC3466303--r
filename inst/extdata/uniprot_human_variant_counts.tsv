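# Published counts of curated human protein variations by class
# (deleterious = disease-associated, neutral = common polymorphism).
variation_type	deleterious	neutral
Single amino acid substitutions	20821	36825
Deletions	652	77
Insertions	110	61
Replacements	79	59
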