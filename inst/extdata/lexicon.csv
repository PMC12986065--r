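surface,concept
murphy sign,murphy_sign
murphys sign,murphy_sign
murphy sign positive,murphy_sign
murphys sign positive,murphy_sign
positive murphy sign,murphy_sign
positive murphys sign,murphy_sign
inspiratory arrest on palpation,murphy_sign
sonographic murphy sign,sonographic_murphy
sonographic murphys sign,sonographic_murphy
right upper quadrant pain,ruq_pain
ruq pain,ruq_pain
pain in the right upper quadrant,ruq_pain
right upper quadrant tenderness,ruq_tenderness
ruq tenderness,ruq_tenderness
tenderness in the right upper quadrant,ruq_tenderness
abdominal tenderness,ruq_tenderness
palpable mass,palpable_mass
palpable tender mass,palpable_mass
palpable mass in the right upper quadrant,palpable_mass
mass in the right upper quadrant,palpable_mass
distended gallbladder,enlarged_gb
enlarged gallbladder,enlarged_gb
gallbladder distension,enlarged_gb
pericholecystic fluid,pericholecystic_fluid
pericholecystic fluid collection,pericholecystic_fluid
gallstones,gallstones
gallstone,gallstones
multiple gallstones,gallstones
cholelithiasis,gallstones
incarcerated gallstone,incarcerated_stone
incarcerated stone,incarcerated_stone
impacted gallstone,incarcerated_stone
impacted stone in the gallbladder neck,incarcerated_stone
stone impacted in the gallbladder neck,incarcerated_stone
debris echo,debris_echo
biliary sludge with debris echo,debris_echo
intramural gas,intramural_gas
gas within the gallbladder wall,intramural_gas
gas in the gallbladder wall,intramural_gas
emphysematous changes of the gallbladder wall,intramural_gas
wall discontinuity,wall_discontinuity
areas of discontinuity,wall_discontinuity
gallbladder wall discontinuity,wall_discontinuity
focal wall defect,wall_discontinuity
irregular gallbladder wall thickening,irregular_wall
irregular wall thickening,irregular_wall
pericholecystic abscess,pericholecystic_abscess
hepatic abscess,hepatic_abscess
liver abscess,hepatic_abscess
biliary peritonitis,biliary_peritonitis
bile peritonitis,biliary_peritonitis
gallbladder perforation,gb_perforation
perforated gallbladder,gb_perforation
perforation of the gallbladder,gb_perforation
gallbladder mass,gb_mass
mass replacing the gallbladder,gb_mass
infiltrative gallbladder mass,gb_mass
cholecystobiliary fistula,cholecystobiliary_fistula
cholecystocholedochal fistula,cholecystobiliary_fistula
fistulous communication between the gallbladder and the bile duct,cholecystobiliary_fistula
extrinsic compression of the common hepatic duct,cbd_compression
common hepatic duct compression,cbd_compression
compression of the common bile duct,cbd_compression
bile duct compression,cbd_compression
cystic duct leak,bile_leak_cystic_duct
cystic duct stump leak,bile_leak_cystic_duct
leak from the cystic duct stump,bile_leak_cystic_duct
bile leak from the cystic duct,bile_leak_cystic_duct
lateral injury to the extrahepatic bile duct,cbd_lateral_injury
lateral bile duct injury,cbd_lateral_injury
partial lateral injury of the common bile duct,cbd_lateral_injury
transection of the common bile duct,cbd_transection
bile duct transection,cbd_transection
complete transection of the common hepatic duct,cbd_transection
confusion,decreased_consciousness
confused,decreased_consciousness
decreased level of consciousness,decreased_consciousness
altered mental status,decreased_consciousness
lethargy,decreased_consciousness
lethargic,decreased_consciousness
obtunded,decreased_consciousness
oliguria,oliguria
oliguric,oliguria
decreased urine output,oliguria
anuria,oliguria
norepinephrine,norepinephrine_any
noradrenaline,norepinephrine_any
norepinephrine infusion,norepinephrine_any
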