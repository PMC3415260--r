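aaliyah
aaliyh
aalyah
agnes
agns
alce
alic
alice
aliyah
allisn
allison
allson
amand
amanda
amin
amina
amna
amnda
amy
andra
andre
andrea
angel
angla
ann
anna
anne
anni
annie
ashley
ashly
astrd
astrid
babs
barb
barbar
barbara
barbra
batrice
bbs
bcca
bcky
beatrce
beatric
beatrice
becc
becca
becky
berth
bertha
beth
betrice
betsy
betty
beverly
bevrly
bnnie
bonne
bonni
bonnie
brb
brbara
brdget
brend
brenda
bridget
bridgt
brnda
brtha
bth
btsy
btty
bverly
camil
camila
camla
carl
carlyn
carmen
carmn
carol
carolyn
carre
carri
carrie
cat
catherin
catherine
catherne
cathrine
cathy
charle
charli
charlie
charlott
charlotte
charltte
cheryl
chris
chrissy
christin
christina
christine
christna
christne
christy
chrlie
chrlotte
chrs
chrssy
chrstina
chrstine
chrsty
chryl
cill
cilla
cindy
clla
clleen
cmila
cndy
cnnie
colleen
collen
conne
conni
connie
crmen
crol
crolyn
crrie
crystal
crystl
ctherine
cthy
cyntha
cynthi
cynthia
dana
dane
dbbie
dborah
dbra
deb
debbe
debbi
debbie
deborah
deborh
debr
debra
debrah
denis
denise
dense
dian
diana
diane
din
dina
dine
dlores
dna
dnise
dnna
dolores
dolors
dolres
donn
donna
doris
dorothy
dors
dorthy
dot
dotte
dotti
dottie
dris
drothy
dttie
dwn
edith
edn
edna
edth
elain
elaine
elane
elanor
eleanor
eleanr
elen
elena
elenor
eline
eliz
eliza
elizabeth
elizabth
elizbeth
elle
ellen
elli
ellie
elln
elna
elza
elzabeth
em
emily
emly
emmy
erca
eric
erica
esmerald
esmeralda
esmerlda
esmralda
esther
esthr
ethel
ethl
evelyn
evlyn
fatim
fatima
fatma
florenc
florence
flornce
flrence
fran
frances
francs
franne
franni
frannie
frey
freya
frn
frnces
frnnie
frya
ftima
gadalupe
gail
gal
geraldin
geraldine
geraldne
gerldine
gil
gladys
gldys
glora
glori
gloria
glria
graldine
gret
greta
grta
guadalpe
guadalup
guadalupe
guadlupe
gudalupe
gwen
gwendlyn
gwendolyn
gwn
gwndolyn
hather
hazel
hazl
heather
heathr
hether
hzel
ingrd
ingrid
iren
irene
irin
irina
irna
irne
isabell
isabella
isablla
isbella
jacke
jacki
jackie
jacqeline
jacquelin
jacqueline
jacquelne
jacquline
jance
jane
janet
janic
janice
janne
jant
jckie
jcqueline
jdith
jdy
jean
jen
jennfer
jennifer
jennifr
jenny
jess
jessca
jesse
jessi
jessic
jessica
jessie
jill
jlia
jlie
jll
jne
jnet
jnice
jnnifer
jnny
jo
joan
joann
joanne
jon
jonne
jose
josephin
josephine
josephne
josi
josie
josphine
joyc
joyce
jsephine
jsie
jss
jssica
jssie
judith
judth
judy
jula
jule
juli
julia
julie
jyce
kar
kara
karen
karn
kat
katarin
katarina
katarna
kate
kath
katherin
katherine
katherne
kathleen
kathlen
kathrine
kathryn
kathy
kati
katie
katrina
katy
katya
kay
keish
keisha
kelly
kesha
kim
kimberly
kimbrly
kimmy
kisha
kitty
klly
kmberly
kmmy
kra
kren
kristen
kristn
krsten
ktarina
kte
kth
ktherine
kthleen
kthryn
kthy
ktie
ktty
ktya
lara
laren
latoy
latoya
latya
laur
laura
lauren
laurn
lbby
lcille
lcy
leil
leila
lela
len
lena
libby
lila
lillan
lillian
lillin
lind
linda
lis
lisa
liz
lizze
lizzi
lizzie
lllian
lna
lnda
lois
loise
lor
lori
lotte
lotti
lottie
louis
louise
louse
lri
lsa
ltoya
lttie
lu
lucill
lucille
luclle
lucy
luise
lura
luren
lzzie
madg
madge
magdalen
magdalena
magdalna
magdlena
magge
maggi
maggie
mandy
mara
mare
mareen
marg
margaret
margart
marge
margret
mari
maria
marie
marilyn
marjore
marjori
marjorie
marjrie
marlyn
mart
marta
marth
martha
mary
maureen
mauren
mchele
mchelle
mdge
meg
megan
megn
mei
mel
meliss
melissa
melssa
merdith
meredith
meredth
mgan
mgdalena
mggie
michel
michele
michell
michelle
michle
michlle
mildrd
mildred
missy
mldred
mlissa
mndy
mnica
monca
monic
monica
mredith
mrgaret
mrge
mria
mrie
mrilyn
mrjorie
mrta
mrtha
mry
mssy
mureen
nancy
nat
natale
natali
natalie
natash
natasha
natlie
natsha
ncole
nell
nicle
nicol
nicole
nll
nncy
noor
nora
norm
norma
nra
nrma
ntalie
ntasha
olg
olga
pala
paline
pam
pamel
pamela
pamla
pammy
pat
patrcia
patrica
patrici
patricia
patty
paula
paulin
pauline
paulne
peggy
pggy
phyllis
phylls
pmela
pmmy
priscill
priscilla
prisclla
priy
priya
prscilla
prya
ptricia
ptty
pula
puline
rachel
rachl
rbecca
rbin
rby
rchel
rebcca
rebecc
rebecca
rit
rita
rnnie
robin
robn
ronne
ronni
ronnie
ros
rosa
rosari
rosario
rosaro
rose
rosrio
rsa
rsario
rse
rta
rth
ruby
ruth
sandr
sandra
sar
sara
sarah
sarh
sfia
shannn
shannon
sharn
sharon
sheil
sheila
shela
shelly
sherry
shila
shirley
shirly
shlly
shnnon
shrley
shron
shrry
sibhan
siobhan
siobhn
sndra
sobhan
sofa
sofi
sofia
sra
srah
ssan
ssie
steff
steffi
steph
stephane
stephani
stephanie
stephnie
stffi
stph
stphanie
sue
susan
suse
susi
susie
susn
suzann
suzanne
suze
suzi
suzie
suznne
suzy
svetlan
svetlana
svetlna
svtlana
szanne
szie
szy
tammy
teres
teresa
tersa
tffany
theres
theresa
thersa
thresa
tiffany
tiffny
tin
tina
tmmy
tna
tracy
trcia
trcy
tresa
trica
trici
tricia
trish
trsh
valentin
valentina
valentna
valere
valeri
valerie
valntina
valrie
vaness
vanessa
vanssa
ver
vera
vernica
veronca
veronic
veronica
vivan
vivian
vivin
vlentina
vlerie
vnessa
vra
vronica
vvian
wand
wanda
wendy
wnda
wndy
yki
ylanda
yoland
yolanda
yolnda
yuk
yuki
yvnne
yvonn
yvonne
zainab
zainb
zanab
zinab
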