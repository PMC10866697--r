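symbol	type	place	manner	vowel_height	cardinal_class
P	consonant	bilabial	stop		
B	consonant	bilabial	stop		
M	consonant	bilabial	nasal		
W	consonant	bilabial	glide		
F	consonant	labiodental	fricative		
V	consonant	labiodental	fricative		
TH	consonant	dental	fricative		
DH	consonant	dental	fricative		
T	consonant	alveolar	stop		
D	consonant	alveolar	stop		
S	consonant	alveolar	fricative		
Z	consonant	alveolar	fricative		
N	consonant	alveolar	nasal		
L	consonant	alveolar	liquid		
R	consonant	alveolar	liquid		
SH	consonant	postalveolar	fricative		
ZH	consonant	postalveolar	fricative		
CH	consonant	postalveolar	affricate		
JH	consonant	postalveolar	affricate		
Y	consonant	palatal	glide		
K	consonant	velar	stop		
G	consonant	velar	stop		
NG	consonant	velar	nasal		
HH	consonant	glottal	fricative		
IY	vowel			high	i
IH	vowel			high	i
EY	vowel			mid_low	e
EH	vowel			mid_low	e_open
ER	vowel			mid_low	e_open
AE	vowel			mid_low	a
AY	vowel			mid_low	a
AW	vowel			mid_low	a
AA	vowel			mid_low	alpha
AH	vowel			mid_low	alpha
AO	vowel			mid_low	o_open
OY	vowel			mid_low	o_open
OW	vowel			mid_low	o
UH	vowel			high	u
UW	vowel			high	u
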