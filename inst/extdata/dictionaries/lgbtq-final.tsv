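#! name: lgbtq
#! iteration: final
# LGBTQ+ identity-disclosure lexicon, final iteration.
# "Gay" and "Trans" still match but carry quality_check status: their hits
# require manual verification ("Gay" occurs as a legal first or last name;
# "trans" appears inside hyphenated medical compounds such as
# trans-metatarsal and trans-abdominal).
# Columns: surface <TAB> match_type <TAB> status
AFAB	whole_word	active
AMAB	whole_word	active
Asexual	whole_word	active
Assigned female at birth	phrase	active
Assigned male at birth	phrase	active
Bisexual	whole_word	active
Bottom surg	phrase_prefix	active
Drag p	phrase_prefix	active
Drag q	phrase_prefix	active
Dysphoria	whole_word	active
FTM	whole_word	active
Gay	whole_word	quality_check
Gender-aff	phrase_prefix	active
Gender aff	phrase_prefix	active
Gender confirmation	phrase	active
Gender dysphoria	phrase	active
Gender euphoria	phrase	active
Gender f	phrase_prefix	active
Gender non	phrase_prefix	active
Gender transition	phrase	active
Genderqueer	whole_word	active
Her girlfriend	phrase	active
Her wife	phrase	active
His boyfriend	phrase	active
His husband	phrase	active
Lesbian	whole_word	active
LGBT	whole_word	active
Mx.	whole_word	active
Ne/	pronoun_slash	active
Non-binary	phrase	active
Nonbinary	whole_word	active
QTPOC	whole_word	active
Queer	whole_word	active
Trans	whole_word	quality_check
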