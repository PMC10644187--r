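#! name: lgbtq
#! iteration: initial
# LGBTQ+ identity-disclosure lexicon, initial iteration (pre-refinement).
# Columns: surface <TAB> match_type <TAB> status
2-spirit	phrase	active
2 spirit	phrase	active
2S	whole_word	active
Ace	whole_word	active
AFAB	whole_word	active
Agender	whole_word	active
AMAB	whole_word	active
Aromantic	whole_word	active
Asexual	whole_word	active
Assigned female at birth	phrase	active
Assigned male at birth	phrase	active
Bigender	whole_word	active
Bisexual	whole_word	active
Bottom surg	phrase_prefix	active
Demi	whole_word	active
Drag k	phrase_prefix	active
Drag p	phrase_prefix	active
Drag q	phrase_prefix	active
Dyke	whole_word	active
Dysphoria	whole_word	active
Enby	whole_word	active
Ey/	pronoun_slash	active
Fag	whole_word	active
Femme	whole_word	active
Fluid	whole_word	active
Fruity	whole_word	active
FTM	whole_word	active
Gay	whole_word	active
Gender-aff	phrase_prefix	active
Gender aff	phrase_prefix	active
Gender confirmation	phrase	active
Gender dysphoria	phrase	active
Gender euphoria	phrase	active
Gender f	phrase_prefix	active
Gender non	phrase_prefix	active
Gender queer	phrase	active
Gender transition	phrase	active
Genderf	whole_word	active
Genderqueer	whole_word	active
GNC	whole_word	active
Her girlfriend	phrase	active
Her wife	phrase	active
His boyfriend	phrase	active
His husband	phrase	active
HRT	whole_word	active
Intersex	whole_word	active
Lesbian	whole_word	active
LGBT	whole_word	active
Masc	whole_word	active
MTF	whole_word	active
Mx.	whole_word	active
NB	whole_word	active
Ne/	pronoun_slash	active
Non-binary	phrase	active
Nonbinary	whole_word	active
Omnigender	whole_word	active
Pansexual	whole_word	active
Partner	whole_word	active
Phalloplasty	whole_word	active
Poly	whole_word	active
QTPOC	whole_word	active
Queer	whole_word	active
Same-gender loving	phrase	active
Sex reassignment	phrase	active
Sexual and gender minority	phrase	active
SGM	whole_word	active
They/	pronoun_slash	active
Top surgery	phrase	active
Trans	whole_word	active
Transgender	whole_word	active
Transitioning	whole_word	active
Transsexual	whole_word	active
Two-spirit	phrase	active
Two spirit	phrase	active
Vaginoplasty	whole_word	active
Ve/	pronoun_slash	active
Xe/	pronoun_slash	active
Zie/	pronoun_slash	active
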