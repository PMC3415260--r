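_
a
e
s
n
o
a_
l
r
d
i
s_
c
u
t
_l
e_
m
o_
_c
la
p
_d
en
_la
de
as
n_
os
an
er
la_
os_
_de
as_
_la_
b
de_
_de_
_e
_m
_p
_s
ra
da
ad
es
co
do
na
nt
ue
v
_a
ca
g
ie
_t
do_
lo
mi
ta
te
y
r_
re
un
y_
_co
_lo
_y
_y_
ab
j
los
los_
na_
on
se
_ca
_los
_los_
_u
_un
_v
am
ci
da_
ent
or
q
qu
í
ía
ía_
_es
_se
ana
ar
ce
con
el
era
es_
ia
in
le
ma
nd
no
nte
po
que
sa
ue_
ó
_con
_las
_las_
_q
_qu
_que
_que_
_r
cer
ec
em
en_
id
ien
las
las_
ll
me
mp
ndo
ndo_
nta
nte_
on_
pa
que_
ro
te_
ti
tr
á
_a_
_el
_en
_g
_ma
_me
_mi
_pa
_re
_su
_vi
aba
ac
ada
and
ando
ando_
ba
bi
cad
el_
ente
ente_
ero
h
ida
ida_
ig
ió
l_
or_
pu
ra_
ran
ri
su
us
vi
_cam
_ci
_con_
_cu
_el_
_en_
_est
_f
_ge
_gen
_h
_po
_por
_por_
_pu
_pue
_se_
_sus
_sus_
_te
_ti
_tie
_una
_una_
_ve
ada_
ade
ado
ado_
aj
al
ami
ana_
ar_
cam
con_
cu
di
ej
emp
era_
eros
eros_
est
f
ge
gen
go
ic
ión
ión_
ja
li
lle
man
min
mpo
nc
no_
ntan
om
pi
por
por_
pr
pue
rec
ros
ros_
rt
se_
so
st
sus
sus_
tan
tie
to
tra
ud
una
una_
us_
va
ve
ás
ás_
ñ
ón
ón_
_ab
_am
_ami
_amig
_b
_cad
_cada
_camb
_ce
_cer
_ciu
_ciud
_com
_cua
_cuan
_di
_do
_esta
_fa
_gent
_hu
_le
_ll
_lle
_llev
_má
_más
_más_
_n
_pas
_pasa
_pr
_rec
_reco
_sa
_sal
_sem
_sema
_si
_tiem
_to
_tod
_toda
_tr
_un_
_uno
_ven
_vid
_vida
aba_
abr
abri
aci
ació
ación
ad_
ader
aje
ajer
ajero
amb
ambi
ambia
amig
an_
anas
anas_
ano
ano_
ant
ante
art
asa
av
aví
avía
avía_
añ
ba_
bia
bl
br
bri
bí
bía
bía_
cada
cada_
cado
cado_
camb
cambi
cie
ciu
ciud
ciuda
ció
ción
ción_
com
cor
cos
cr
cua
cuan
cuand
d_
dad
dad_
das
das_
dav
daví
davía
der
des
eco
ecor
eg
ejo
ema
eman
emana
empo
empo_
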