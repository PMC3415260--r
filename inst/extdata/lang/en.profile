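_
e
t
a
h
r
s
n
o
i
e_
l
_t
d
th
he
_th
the
w
s_
_the
d_
he_
_a
_the_
the_
n_
m
_w
f
g
p
in
t_
_s
er
y
y_
ha
re
u
en
nd
b
_o
ar
at
c
r_
an
le
ng
_f
_h
_c
_i
_m
_p
ed
ed_
er_
ing
k
st
v
_an
_and
_and_
_l
and
and_
as
en_
es
g_
ing_
li
nd_
ng_
_a_
_ha
_to
a_
ea
it
ll
o_
or
to
ve
_b
ad
at_
ee
ge
il
is
ly
ly_
me
on
ow
pe
re_
ri
te
_d
_e
_mo
_of
_tha
_to_
_wa
_wh
al
be
ev
eve
hat
in_
le_
mo
of
op
ou
pl
ple
ro
rs
rs_
sh
st_
tha
ti
to_
ur
wa
wh
_be
_co
_ev
_eve
_g
_li
_pa
_r
_st
_that
_wi
are
as_
co
el
ers
ers_
es_
et
fe
hat_
her
ie
k_
l_
ld
ne
pa
ra
rn
ry
ry_
se
su
that
that_
ts
ts_
wi
wo
_ar
_are
_are_
_fi
_fr
_had
_had_
_in
_in_
_is
_is_
_it
_le
_of_
_on
_pe
_peo
_peop
_re
_sh
_su
_we
_whe
_when
_wit
_with
_wo
ab
ad_
ai
are_
ay
ay_
bo
da
de
ds
ds_
ear
eo
eop
eopl
eople
ever
f_
fi
fr
gr
had
had_
hed
hed_
hen
hen_
her_
hi
id
ill
is_
ith
ke
ld_
ll_
ma
ni
od
of_
om
on_
oo
opl
ople
ople_
os
own
own_
peo
peop
peopl
ple_
she
ther
tr
un
und
ut
ver
w_
we
whe
when
when_
wit
with
wn
wn_
_ab
_abo
_abou
_bee
_been
_ca
_da
_du
_dur
_duri
_even
_ever
_fa
_fin
_fri
_frie
_gr
_has
_has_
_its
_its_
_lif
_life
_ma
_mor
_mos
_most
_pas
_sl
_sm
_sti
_stil
_tr
_tra
_was
_was_
_wee
_week
abo
abou
about
ag
all
an_
ap
ate
ati
atio
ation
bee
been
been_
bou
bout
bout_
br
ca
ch
day
day_
de_
di
din
ding
ding_
du
dur
duri
durin
eek
eek_
een
een_
ef
ek
ek_
ell
em
end
ends
ends_
ene
ery
ery_
est
est_
even
every
ew
ew_
fa
fe_
fin
fo
for
fri
frie
frien
ft
ge_
gre
h_
han
has
has_
hin
ho
ib
ien
iend
iends
if
ife
ife_
ill_
im
io
ion
ion_
ish
ishe
ished
ith_
its
its_
la
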