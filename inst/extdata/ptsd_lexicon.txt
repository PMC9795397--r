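# PTSD surface-form lexicon: one variant per line, matched case-insensitively
# at word boundaries and rewritten to the canonical token "ptsd" before any
# other cleanup.  Longest variant wins where variants overlap.  Edit or
# replace this file to supply a site-specific list of abbreviations,
# misspellings and phrases.
ptsd
p.t.s.d.
p.t.s.d
p t s d
ptss
ptds
pstd
tpsd
post traumatic stress disorder
posttraumatic stress disorder
post-traumatic stress disorder
post tramatic stress disorder
posttraumatic stress
post traumatic stress
post-traumatic stress
post traumatic stress d/o
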