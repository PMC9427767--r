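# Description-length constants, in bits. One place, overridable; echoed into
# result files for provenance.
rule_base: 4
feature_literal: 1
kleene_star: 2
# each trigger element pays a slot cost (continue-tag + brackets) on top of
# its literals; the word boundary is a bare terminator symbol and costs less,
# so "any segment follows" is never cheaper than "word-final"
trigger_element: 2
boundary: 1
alpha_variable: 2
lexicon_phoneme: 3
insert_phoneme: 3
copy_change: 2
# "flat": lexicon_phoneme bits per phoneme. "uniform": log2(|inventory|) + 1
# bits per phoneme (the +1 is a continue/stop bit, making the stem code a
# subprobability over all finite strings).
phoneme_coding: flat
allow_star: yes
allow_features: yes
max_rules: 2
max_stem_len: 4
max_affix_len: 1
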