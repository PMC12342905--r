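component,fiscal_year,amount_gbp,price_year
inpatient,2015,5449545832.19,2022
inpatient,2019/20,5902562012.59,2022
inpatient,2020/21,6258547282.76,2022
inpatient,2021/22,6732456821.82,2022
outpatient,2015,899427786.19,2022
outpatient,2019/20,900995134.97,2022
outpatient,2020/21,924269717.97,2022
outpatient,2021/22,1010695676.09,2022
a_and_e,2015,333955900.58,2022
a_and_e,2019/20,357042291.74,2022
a_and_e,2020/21,392362590.87,2022
a_and_e,2021/22,327626962.37,2022
primary_care,2015,1372554805.84,2022
primary_care,2019/20,1423677763.98,2022
primary_care,2020/21,1265861038.04,2022
primary_care,2021/22,1555641199.16,2022
medications,2015,2288700449.83,2022
medications,2019/20,1805967156.62,2022
medications,2020/21,1853979414.91,2022
medications,2021/22,1940427596.98,2022
devices,2019/20,307116365.46,2022
devices,2020/21,243893010.21,2022
devices,2021/22,404371349.20,2022
ltc,2019/20,3903440803.45,2022
ltc,2020/21,4384334226.00,2022
ltc,2021/22,4648757713.68,2022
total_direct_core,2015,10344184774.63,2022
total_direct_core,2019/20,10390244359.89,2022
total_direct_core,2020/21,10695020044.55,2022
total_direct_core,2021/22,11566848256.42,2022
total_direct,2019/20,14600801528.80,2022
total_direct,2020/21,15323247280.76,2022
total_direct,2021/22,16619977319.30,2022
morbidity,2015,2134749896.72,2022
morbidity,2019/20,1804975954.90,2022
morbidity,2020/21,1371129207.87,2022
morbidity,2021/22,1480608481.76,2022
mortality,2015,5196227187.18,2022
mortality,2019/20,4170139187.51,2022
mortality,2020/21,4472253912.71,2022
mortality,2021/22,4543976274.97,2022
informal_care,2015,4663386830.99,2022
informal_care,2019/20,5714817518.95,2022
informal_care,2020/21,5433376101.67,2022
informal_care,2021/22,6376929218.16,2022
total_indirect,2015,11994363914.90,2022
total_indirect,2019/20,11689932661.36,2022
total_indirect,2020/21,11276759222.25,2022
total_indirect,2021/22,12401513974.89,2022
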