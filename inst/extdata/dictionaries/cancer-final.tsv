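#! name: cancer
#! iteration: final
# Cancer lexicon, final iteration. The seven treatment words eliminated
# for matching other-disease campaigns (chemo, chemotherap, immuno therap,
# immunotherap, mastectomy, radiation therap, radiotherap) are absent.
# "lukemia germ cell tumor" is transcribed verbatim from the source list;
# it may be two run-together terms in the source formatting.
# Columns: surface <TAB> match_type <TAB> status
adenocarcinoma	whole_word	active
astrocytoma	whole_word	active
cáncer	whole_word	active
carcinoid	whole_word	active
carcinoma	whole_word	active
clear cell	phrase	active
desmoplastic	whole_word	active
ductal carcinoma	phrase	active
ductile carcinoma	phrase	active
ependymoma	whole_word	active
glioblastoma	whole_word	active
histiocytosis	whole_word	active
langerhans	whole_word	active
leukemia	prefix_stem	active
luekemia	prefix_stem	active
lukemia germ cell tumor	phrase	active
lumpectomy	whole_word	active
lymphoma	whole_word	active
malignan	prefix_stem	active
medulloblastoma	whole_word	active
melanoma	whole_word	active
myeloma	whole_word	active
myloma	whole_word	active
neruoblastoma	whole_word	active
neurblastoma	whole_word	active
neuroblastoma	whole_word	active
neuroendocrine tumor	phrase	active
non-hodgkins lymphoma	phrase	active
non hodgkins lymphoma	phrase	active
nonhodgkins lymphoma	phrase	active
nueroblastoma	whole_word	active
nuroblastoma	whole_word	active
oligodendroglioma	whole_word	active
renal cell	phrase	active
retinoblastoma	whole_word	active
rhabdomyosarcoma	whole_word	active
rhabdomyosaroma	whole_word	active
sarcoma	whole_word	active
seminoma	whole_word	active
squamous cell	phrase	active
thymoma	whole_word	active
wilm's tumor	phrase	active
wilms tumor	phrase	active
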