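a
ao
aos
as
até
com
como
da
das
de
dela
dele
do
dos
e
ela
ele
em
entre
era
é
essa
esse
esta
este
eu
foi
há
isso
isto
já
mais
mas
me
mesmo
meu
minha
muito
na
não
nas
nem
no
nos
nós
o
os
ou
para
pela
pelo
por
quando
que
quem
se
sem
ser
seu
sua
também
te
tem
um
uma
você
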