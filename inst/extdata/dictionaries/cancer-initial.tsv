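#! name: cancer
#! iteration: initial
# Cancer lexicon, initial iteration (refined from a previously published
# dictionary). Truncated stems (chemotherap, malignan, ...) use prefix
# matching so inflected forms hit.
# Two entries below appear run together in the source list and are
# transcribed verbatim; the final iteration prints them as separate terms:
#   "non hodgkins lymphoma nonhodgkins lymphoma"
#   "rhabdomyosarcoma rhabdomyosaroma"
# "lukemia germ cell tumor" is likewise transcribed verbatim; it may be two
# run-together terms in the source formatting.
# Columns: surface <TAB> match_type <TAB> status
adenocarcinoma	whole_word	active
astrocytoma	whole_word	active
cáncer	whole_word	active
carcinoid	whole_word	active
carcinoma	whole_word	active
chemo	whole_word	active
chemotherap	prefix_stem	active
clear cell	phrase	active
desmoplastic	whole_word	active
ductal carcinoma	phrase	active
ductile carcinoma	phrase	active
ependymoma	whole_word	active
glioblastoma	whole_word	active
histiocytosis	whole_word	active
immuno therap	phrase_prefix	active
immunotherap	prefix_stem	active
langerhans	whole_word	active
leukemia	prefix_stem	active
luekemia	prefix_stem	active
lukemia germ cell tumor	phrase	active
lumpectomy	whole_word	active
lymphoma	whole_word	active
malignan	prefix_stem	active
mastectomy	whole_word	active
medulloblastoma	whole_word	active
melanoma	whole_word	active
myeloma	whole_word	active
myloma	whole_word	active
neruoblastoma	whole_word	active
neurblastoma	whole_word	active
neuroblastoma	whole_word	active
neuroendocrine tumor	phrase	active
non-hodgkins lymphoma	phrase	active
non hodgkins lymphoma nonhodgkins lymphoma	phrase	active
nueroblastoma	whole_word	active
nuroblastoma	whole_word	active
oligodendroglioma	whole_word	active
radiation therap	phrase_prefix	active
radiotherap	prefix_stem	active
renal cell	phrase	active
retinoblastoma	whole_word	active
rhabdomyosarcoma rhabdomyosaroma	phrase	active
sarcoma	whole_word	active
seminoma	whole_word	active
squamous cell	phrase	active
thymoma	whole_word	active
wilm's tumor	phrase	active
wilms tumor	phrase	active
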