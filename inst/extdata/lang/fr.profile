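_
e
s
a
t
n
l
i
e_
s_
r
u
o
d
t_
es
_l
es_
le
_d
m
p
c
en
nt
v
_le
_de
de
nt_
_p
_s
re
_e
an
n_
q
qu
é
la
on
_c
les
les_
a_
g
te
_a
_la
_la_
ai
et
la_
_de_
_les
_les_
_v
de_
er
in
le_
se
ue
_q
_qu
ent
f
il
re_
_m
_r
h
ie
it
ll
que
_et
_et_
_f
_se
_t
ar
ch
ent_
et_
eu
ge
lle
ma
ne
ou
so
ti
é_
_pe
_so
_vi
ant
b
co
d_
em
ne_
oi
on_
pe
tr
u_
ue_
ve
vi
_ch
_le_
_u
_un
ant_
av
da
ill
is
mi
nd
ns
pl
que_
r_
rs
un
ur
_av
_b
_cha
_des
_des_
_o
_pl
_re
cha
dan
des
des_
ha
ille
in_
it_
lle_
lu
mp
ont
pa
rs_
son
ut
va
_bo
_en
_g
_ma
_pen
_plu
_que
_son
_un_
ag
ait
ait_
am
au
ava
bo
dant
dant_
er_
eur
ien
ir
is_
me
nda
ndan
ndant
ns_
ont_
ouv
ouve
pen
plu
ra
ri
rt
ta
te_
tre
un_
uv
uve
vai
è
_au
_ava
_ce
_co
_d_
_fa
_fe
_pa
_pend
_plus
_que_
_sont
_te
_tr
_vie
_vil
_vill
_vo
age
aie
aien
aient
ain
ami
and
ang
ange
ard
at
ati
au_
avai
ce
con
di
ec
el
ema
emp
end
enda
endan
ens
erm
est
eurs
eurs_
fa
fe
ient
ient_
ille_
ine
io
l_
lus
lus_
man
mps
mps_
na
nc
ng
nge
nn
nte
ois
or
par
pend
penda
plus
plus_
ps
ps_
rd
res
rm
ses
ses_
si
sont
sont_
st
tem
tes
tes_
tt
ues
ues_
ul
urs
urs_
us
us_
ut_
ux
ux_
ven
vie
vil
vill
vo
x
x_
_am
_ami
_au_
_avai
_ave
_avec
_bou
_chan
_chaq
_con
_di
_enc
_enco
_es
_est
_est_
_fer
_ferm
_fu
_fut
_fut_
_ge
_gen
_gens
_i
_il
_mat
_mati
_mo
_moi
_n
_on
_on_
_ou
_par
_qu_
_qua
_quan
_ru
_rue
_se_
_sem
_sema
_ses
_ses_
_sou
_souv
_tem
_temp
_tra
_une
_une_
_vie_
_voy
_voya
_é
ageu
ageur
aine
aine_
and_
anger
ans
ans_
aq
aqu
aque
aque_
arc
ard_
art
atin
atin_
ave
avec
avec_
bou
c_
chan
chang
chaq
chaqu
cor
core
core_
ea
ec_
ei
eil
eill
eille
ell
elle
emai
emain
emps
emps_
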