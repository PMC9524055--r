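alerte
avec
cas
ce
cette
choléra
confinement
confirmés
contre
dans
dengue
des
décès
dépistage
ebola
fièvre
grippe
hôpital
les
malades
maladie
mesures
ministère
nouveaux
paludisme
patients
peste
plus
polio
pour
premiers
publique
rage
riposte
rougeole
sanitaire
santé
selon
signalés
situation
sont
surveillance
symptômes
vaccin
virus
épidémie
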