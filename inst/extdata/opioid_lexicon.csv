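surface_term,canonical_drug,receptor_class,synthesis_class
heroin,heroin,heroin,heroin
heroine,heroin,heroin,heroin
herion,heroin,heroin,heroin
smack,heroin,heroin,heroin
morphine,morphine,full_agonist,natural_semisynthetic
morfine,morphine,full_agonist,natural_semisynthetic
fentanyl,fentanyl,full_agonist,synthetic
fentanil,fentanyl,full_agonist,synthetic
fentynal,fentanyl,full_agonist,synthetic
fent,fentanyl,full_agonist,synthetic
china white,fentanyl,full_agonist,synthetic
oxycodone,oxycodone,full_agonist,natural_semisynthetic
oxycontin,oxycodone,full_agonist,natural_semisynthetic
percocet,oxycodone,full_agonist,natural_semisynthetic
oxys,oxycodone,full_agonist,natural_semisynthetic
naloxone,naloxone,antagonist,natural_semisynthetic
narcan,naloxone,antagonist,natural_semisynthetic
hydrocodone,hydrocodone,full_agonist,natural_semisynthetic
vicodin,hydrocodone,full_agonist,natural_semisynthetic
hydros,hydrocodone,full_agonist,natural_semisynthetic
methadone,methadone,full_agonist,excluded
methadon,methadone,full_agonist,excluded
codeine,codeine,full_agonist,natural_semisynthetic
codiene,codeine,full_agonist,natural_semisynthetic
tramadol,tramadol,full_agonist,synthetic
tramadole,tramadol,full_agonist,synthetic
hydromorphone,hydromorphone,full_agonist,natural_semisynthetic
dilaudid,hydromorphone,full_agonist,natural_semisynthetic
oxymorphone,oxymorphone,full_agonist,natural_semisynthetic
opana,oxymorphone,full_agonist,natural_semisynthetic
buprenorphine,buprenorphine,partial_agonist,natural_semisynthetic
suboxone,buprenorphine,partial_agonist,natural_semisynthetic
bupe,buprenorphine,partial_agonist,natural_semisynthetic
loperamide,loperamide,partial_agonist,other_opioid
imodium,loperamide,partial_agonist,other_opioid
naltrexone,naltrexone,antagonist,natural_semisynthetic
vivitrol,naltrexone,antagonist,natural_semisynthetic
pethidine,pethidine,full_agonist,other_opioid
meperidine,pethidine,full_agonist,other_opioid
demerol,pethidine,full_agonist,other_opioid
nalmefene,nalmefene,antagonist,other_opioid
nalbuphine,nalbuphine,mixed_agonist,other_opioid
sufentanil,sufentanil,full_agonist,other_opioid
sufentanyl,sufentanil,full_agonist,other_opioid
butorphanol,butorphanol,mixed_agonist,other_opioid
pentazocine,pentazocine,mixed_agonist,other_opioid
levorphanol,levorphanol,full_agonist,other_opioid
diprenorphine,diprenorphine,antagonist,other_opioid
nalorphine,nalorphine,mixed_agonist,other_opioid
dezocine,dezocine,mixed_agonist,other_opioid
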