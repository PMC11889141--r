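term	class	family	priority
antigen 5	secreted	Antigen-5	0
venom allergen	secreted	Antigen-5	0
apolipoprotein	secreted	Apolipoprotein	0
apolipophorin	secreted	Apolipoprotein	0
amylase	secreted	Amylase	0
maltase	secreted	Maltase	0
alpha-glucosidase	secreted	Maltase	0
acid phosphatase	secreted	Acid phosphatase	0
cathepsin	secreted	Cysteine peptidase	0
cysteine peptidase	secreted	Cysteine peptidase	0
cysteine protease	secreted	Cysteine peptidase	0
dipeptidyl peptidase	secreted	Dipeptidyl peptidase	0
metallopeptidase	secreted	Metallo peptidase	0
metalloprotease	secreted	Metallo peptidase	0
metalloproteinase	secreted	Metallo peptidase	0
trypsin	secreted	Serine peptidase	0
chymotrypsin	secreted	Serine peptidase	0
serine peptidase	secreted	Serine peptidase	0
serine protease	secreted	Serine peptidase	0
clip domain	secreted	Serine peptidase	0
esterase	secreted	Esterase	0
carboxylesterase	secreted	Esterase	0
lipase	secreted	Lipase	0
hormone binding	secreted	Hormone-binding protein	0
hormone-binding	secreted	Hormone-binding protein	0
attacin	secreted	Attacin	0
lectin	secreted	Lectin	0
diptericin	secreted	Diptericin	0
cecropin	secreted	Cecropin	0
lysozyme	secreted	Lysozyme	0
defensin	secreted	Defensin	0
mucin	secreted	Mucin	0
odorant binding	secreted	Odorant-binding protein	0
odorant-binding	secreted	Odorant-binding protein	0
kunitz	secreted	Kunitz	10
kazal	secreted	Kazal	10
cystatin	secreted	Cystatin	10
serpin	secreted	Serpin	10
trypsin inhibitor	secreted	Trypsin-inhibitor like (TIL)	10
trypsin-inhibitor	secreted	Trypsin-inhibitor like (TIL)	10
til domain	secreted	Trypsin-inhibitor like (TIL)	10
occlusion-derived virus	virus	NA	0
per os infectivity	virus	NA	0
nucleopolyhedrovirus	virus	NA	0
hytrosavirus	virus	NA	0
cytochrome c oxidase	Met/Energy	NA	0
atp synthase	Met/Energy	NA	0
nadh dehydrogenase	Met/Energy	NA	0
citrate synthase	Met/Energy	NA	0
malate dehydrogenase	Met/Energy	NA	0
glyceraldehyde-3-phosphate	Met/Energy	NA	0
pyruvate kinase	Met/Energy	NA	0
rna polymerase	transcription machinery	NA	0
transcription factor	transcription machinery	NA	0
zinc finger	transcription machinery	NA	0
homeobox	transcription machinery	NA	0
mediator complex	transcription machinery	NA	0
peptidoglycan recognition	immunity	NA	0
prophenoloxidase	immunity	NA	0
toll-like	immunity	NA	0
spaetzle	immunity	NA	0
relish	immunity	NA	0
ribosomal protein	protein synthesis	NA	0
elongation factor	protein synthesis	NA	0
trna synthetase	protein synthesis	NA	0
translation initiation	protein synthesis	NA	0
signal recognition particle	protein export	NA	0
sec61	protein export	NA	0
coatomer	protein export	NA	0
protein disulfide isomerase	protein export	NA	0
protein kinase	protein modification	NA	0
glycosyltransferase	protein modification	NA	0
protein phosphatase	protein modification	NA	0
prolyl hydroxylase	protein modification	NA	0
proteasome	proteasome	NA	0
ubiquitin	proteasome	NA	0
g protein	signal transduction	NA	0
calmodulin	signal transduction	NA	0
14-3-3	signal transduction	NA	0
adenylate cyclase	signal transduction	NA	0
actin	cytoskeletal	NA	0
tubulin	cytoskeletal	NA	0
myosin	cytoskeletal	NA	0
troponin	cytoskeletal	NA	0
abc transporter	transporters/storage	NA	0
aquaporin	transporters/storage	NA	0
ferritin	transporters/storage	NA	0
solute carrier	transporters/storage	NA	0
histone	nuclear regulation	NA	0
chromatin	nuclear regulation	NA	0
nucleolar	nuclear regulation	NA	0
glucosidase	carbohydrate metabolism	NA	0
glycogen	carbohydrate metabolism	NA	0
hexokinase	carbohydrate metabolism	NA	0
trehalase	carbohydrate metabolism	NA	0
fatty acid synthase	lipid metabolism	NA	0
acyl-coa	lipid metabolism	NA	0
phospholipase	lipid metabolism	NA	0
sphingomyelinase	lipid metabolism	NA	0
aminotransferase	amino acid metabolism	NA	0
glutamine synthetase	amino acid metabolism	NA	0
arginase	amino acid metabolism	NA	0
thymidylate synthase	nucleotide metabolism	NA	0
ribonucleoside diphosphate reductase	nucleotide metabolism	NA	0
dutpase	nucleotide metabolism	NA	0
thymidine kinase	nucleotide metabolism	NA	0
dihydrofolate reductase	nucleotide metabolism	NA	0
cytochrome p450	oxidant metabolism/detoxification	NA	0
glutathione s-transferase	oxidant metabolism/detoxification	NA	0
superoxide dismutase	oxidant metabolism/detoxification	NA	0
catalase	oxidant metabolism/detoxification	NA	0
collagen	extracellular matrix	NA	0
laminin	extracellular matrix	NA	0
peritrophin	extracellular matrix	NA	0
transposase	transposable element	NA	0
reverse transcriptase	transposable element	NA	0
gag-pol	transposable element	NA	0
cyclin	cell cycle	NA	0
cell division cycle	cell cycle	NA	0
heat shock	chaperone	NA	0
chaperonin	chaperone	NA	0
dnaj	chaperone	NA	0
cuticular protein	cuticle	NA	0
chitin synthase	cuticle	NA	0
chitinase	cuticle	NA	0
inhibitor of apoptosis	apoptosis	NA	5
caspase	apoptosis	NA	0
helicase	RNA metabolism	NA	0
splicing factor	RNA metabolism	NA	0
rna-binding	RNA metabolism	NA	0
hypothetical protein	unknown	NA	-5
uncharacterized	unknown	NA	-5
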