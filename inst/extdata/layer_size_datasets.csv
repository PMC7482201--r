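dataset,group,layer,cumulative_size
cellphone_europe_calls,personal,1,2.9
cellphone_europe_calls,personal,2,7.4
cellphone_europe_calls,personal,3,17.7
cellphone_europe_calls,personal,4,43.0
cellphone_europe_calls,personal,5,134.3
cellphone_china,personal,1,2.1
cellphone_china,personal,2,7.3
cellphone_china,personal,3,20.4
cellphone_china,personal,4,54.2
cellphone_china,personal,5,141.4
facebook_1,personal,1,1.7
facebook_1,personal,2,5.3
facebook_1,personal,3,14.9
facebook_1,personal,4,40.9
facebook_2,personal,1,1.5
facebook_2,personal,2,4.3
facebook_2,personal,3,10.7
facebook_2,personal,4,27.0
coauthor_networks,personal,1,2.0
coauthor_networks,personal,2,6.3
coauthor_networks,personal,3,15.8
coauthor_networks,personal,4,37.9
coauthor_networks,personal,5,116.8
personal_average,personal,1,2.0
personal_average,personal,2,5.8
personal_average,personal,3,15.8
personal_average,personal,4,34.6
personal_average,personal,5,148.3
communities_of_practice,community,1,4.0
communities_of_practice,community,2,11.0
communities_of_practice,community,3,30.2
communities_of_practice,community,4,112.2
communities_of_practice,community,5,389.0
communities_of_practice,community,6,1737.8
twitter_communities,community,1,1.6
twitter_communities,community,2,4.5
twitter_communities,community,3,11.2
twitter_communities,community,4,28.3
twitter_communities,community,5,88.3
community_average,community,1,1.6
community_average,community,2,4.6
community_average,community,3,12.8
community_average,community,4,45.5
community_average,community,5,154.4
community_average,community,6,369.5
community_average,community,7,1350.4
multilevel_mammals,mammal,1,3.1
multilevel_mammals,mammal,2,6.9
multilevel_mammals,mammal,3,19.8
multilevel_mammals,mammal,4,47.3
primate_groups,mammal,1,2.3
primate_groups,mammal,2,6.2
primate_groups,mammal,3,15.6
primate_groups,mammal,4,31.3
primate_groups,mammal,5,53.1
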