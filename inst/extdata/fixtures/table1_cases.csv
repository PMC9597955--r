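case_id,label,n_reviews,primary_outcome,primary_intervention,benefit_direction,judged_same_criteria,pilot
bakdach-2020,Bakdach 2020,3,Incidence of white spot lesions,Topical fluoride toothpaste or gel,lower_better,no,yes
chalmers-2015,Chalmers 2015,2,Rate of recurrent instability,Arthroscopic versus open shoulder stabilisation,lower_better,yes,yes
bolland-2014,Bolland 2014,4,Hip fracture,Vitamin D with or without calcium,lower_better,yes,yes
grassi-2018,Grassi 2018,5,Re-operation rate,Patellar resurfacing versus non-resurfacing,lower_better,yes,no
erickson-2015,Erickson 2015,2,Recurrent patellar dislocation,Operative versus non-operative treatment,lower_better,yes,no
chen-p-2019,Chen P 2019,4,Pain by WOMAC total score,Platelet-rich plasma injection,lower_better,yes,no
chen-x-2018,Chen X 2018,5,Short-term VAS pain score,Unilateral versus bilateral kyphoplasty,lower_better,no,no
xu-2017,Xu 2017,5,Fracture non-union,Intramedullary versus plate fixation,lower_better,yes,no
song-2016,Song 2016,6,Bile duct injury,Early versus delayed laparoscopic cholecystectomy,lower_better,yes,no
zhao-2015a,Zhao 2015a,3,Function by constant score,Surgical versus conservative treatment,higher_better,yes,no
tan-2018,Tan 2018,6,Short-term VAS pain score,Unilateral versus bilateral percutaneous balloon kyphoplasty,lower_better,yes,no
poolman-2007,Poolman 2007,3,Knee stability by pivot shift test,Hamstring versus bone-patellar tendon-bone autograft,higher_better,yes,no
mascarenhas-2014,Mascarenhas 2014,3,Function by constant score,Single versus double row rotator cuff repair,higher_better,yes,no
xing-2016,Xing 2016,10,Early and late knee pain,Hyaluronic acid versus placebo,lower_better,yes,no
mascarenhas-2015,Mascarenhas 2015,6,Knee stability by pivot shift test,Single versus double bundle ACL reconstruction,higher_better,yes,no
guo-2018,Guo 2018,4,Disease control rate,Shenyi capsule plus chemotherapy versus chemotherapy,higher_better,yes,no
houck-2017,Houck 2017,5,Range of motion,Early versus delayed motion rehabilitation,higher_better,yes,no
pekala-2019,Pekala 2019,7,Intervertebral disc degeneration,FokI polymorphism,lower_better,no,no
zhiyong-2019,Zhiyong 2019,6,Short-term VAS pain score,Unilateral versus bilateral balloon kyphoplasty,lower_better,no,no
fu-2019,Fu 2019,4,Function by constant score,Surgical versus non-surgical treatment,higher_better,yes,no
zhao-2015b,Zhao 2015b,4,Fracture non-union,Intramedullary nail versus plate fixation,lower_better,yes,no
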