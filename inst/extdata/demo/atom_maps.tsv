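reaction	substrate	product
aldo1	1.1	1.3
aldo1	1.2	1.2
aldo1	1.3	1.1
aldo1	1.4	2.1
aldo1	1.5	2.2
aldo1	1.6	2.3
aldo2	1.1	1.3
aldo2	1.2	1.2
aldo2	1.3	1.1
aldo2	1.4	2.1
aldo2	1.5	2.2
aldo2	1.6	2.3
aldo3	1.1	1.1
aldo3	1.2	1.2
aldo3	1.3	1.3
aldo3	1.4	2.1
aldo3	1.5	2.2
aldo3	1.6	2.3
aldo3	2.1	1.4
aldo3	2.2	1.5
aldo3	2.3	1.6
eno	1.1	1.1
eno	1.2	1.2
eno	1.3	1.3
fbasea	1.1	1.1
fbasea	1.2	1.2
fbasea	1.3	1.3
fbasea	1.4	1.4
fbasea	1.5	1.5
fbasea	1.6	1.6
fbaseb	1.1	1.1
fbaseb	1.2	1.2
fbaseb	1.3	1.3
fbaseb	1.4	1.4
fbaseb	1.5	1.5
fbaseb	1.6	1.6
fruhk	1.1	1.1
fruhk	1.2	1.2
fruhk	1.3	1.3
fruhk	1.4	1.4
fruhk	1.5	1.5
fruhk	1.6	1.6
frutr	1.1	1.1
frutr	1.2	1.2
frutr	1.3	1.3
frutr	1.4	1.4
frutr	1.5	1.5
frutr	1.6	1.6
g6pasea	1.1	1.1
g6pasea	1.2	1.2
g6pasea	1.3	1.3
g6pasea	1.4	1.4
g6pasea	1.5	1.5
g6pasea	1.6	1.6
g6paseb	1.1	1.1
g6paseb	1.2	1.2
g6paseb	1.3	1.3
g6paseb	1.4	1.4
g6paseb	1.5	1.5
g6paseb	1.6	1.6
gapdh	1.1	1.1
gapdh	1.2	1.2
gapdh	1.3	1.3
gka	1.1	1.1
gka	1.2	1.2
gka	1.3	1.3
gka	1.4	1.4
gka	1.5	1.5
gka	1.6	1.6
gkb	1.1	1.1
gkb	1.2	1.2
gkb	1.3	1.3
gkb	1.4	1.4
gkb	1.5	1.5
gkb	1.6	1.6
glctr	1.1	1.1
glctr	1.2	1.2
glctr	1.3	1.3
glctr	1.4	1.4
glctr	1.5	1.5
glctr	1.6	1.6
gp	1.1	1.1
gp	1.2	1.2
gp	1.3	1.3
gp	1.4	1.4
gp	1.5	1.5
gp	1.6	1.6
gpia	1.1	1.1
gpia	1.2	1.2
gpia	1.3	1.3
gpia	1.4	1.4
gpia	1.5	1.5
gpia	1.6	1.6
gpib	1.1	1.1
gpib	1.2	1.2
gpib	1.3	1.3
gpib	1.4	1.4
gpib	1.5	1.5
gpib	1.6	1.6
gs	1.1	1.1
gs	1.2	1.2
gs	1.3	1.3
gs	1.4	1.4
gs	1.5	1.5
gs	1.6	1.6
lactr	1.1	1.1
lactr	1.2	1.2
lactr	1.3	1.3
ldh	1.1	1.1
ldh	1.2	1.2
ldh	1.3	1.3
pfka	1.1	1.1
pfka	1.2	1.2
pfka	1.3	1.3
pfka	1.4	1.4
pfka	1.5	1.5
pfka	1.6	1.6
pfkb	1.1	1.1
pfkb	1.2	1.2
pfkb	1.3	1.3
pfkb	1.4	1.4
pfkb	1.5	1.5
pfkb	1.6	1.6
pgk	1.1	1.1
pgk	1.2	1.2
pgk	1.3	1.3
pglm	1.1	1.1
pglm	1.2	1.2
pglm	1.3	1.3
pglm	1.4	1.4
pglm	1.5	1.5
pglm	1.6	1.6
pgm	1.1	1.1
pgm	1.2	1.2
pgm	1.3	1.3
pk	1.1	1.1
pk	1.2	1.2
pk	1.3	1.3
tim	1.1	1.3
tim	1.2	1.2
tim	1.3	1.1
trik	1.1	1.1
trik	1.2	1.2
trik	1.3	1.3
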