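crop,category,percent_reduction,note
Wheat,none,0,wind/self-pollinated cereal
Rice paddy,none,0,self-pollinated cereal
Maize,none,0,wind-pollinated cereal
Barley,none,0,self-pollinated cereal
Sorghum,none,0,self-pollinated cereal
Millet,none,0,self-pollinated cereal
Oats,none,0,self-pollinated cereal
Rye,none,0,wind-pollinated cereal
Sugar cane,none,0,vegetatively propagated
Sugar beet,none,0,grown for root
Potatoes,none,0,grown for tuber
Cassava,none,0,grown for root
Sweet potatoes,none,0,grown for root
Yams,none,0,grown for tuber
Onions dry,none,0,grown for bulb
Grapes,none,0,self-fertile / parthenocarpic
Olives,none,0,wind-pollinated
Bananas,none,0,parthenocarpic
Groundnuts with shell,little,5,autogamous legume with small insect benefit
Beans dry,little,5,largely autogamous legume
Chick peas,little,2,autogamous legume
Tomatoes,little,8,buzz pollination improves set
Oranges,little,5,many self-fertile citrus cultivars
Soybeans,modest,25,moderately pollinator-dependent oilseed
Rapeseed,modest,25,moderately pollinator-dependent oilseed
Sunflower seed,modest,30,moderately pollinator-dependent oilseed
Oil palm fruit,modest,25,weevil-assisted pollination
Seed cotton,modest,15,partially insect-pollinated
Coconuts,modest,30,partially insect-pollinated palm
Sesame seed,modest,25,partially insect-pollinated oilseed
Coffee green,modest,30,yield gain from bee visitation
Strawberries,modest,25,fruit quality depends on visits
Apples,high,65,orchard fruit requiring cross-pollination
Pears,high,65,orchard fruit requiring cross-pollination
Cherries,high,65,orchard fruit requiring cross-pollination
Almonds with shell,high,60,bee-dependent nut
Mangoes,high,65,insect-pollinated tree fruit
Avocados,high,65,insect-pollinated tree fruit
Cucumbers and gherkins,high,65,cucurbit requiring insect visits
Buckwheat,high,65,insect-pollinated pseudocereal
Cashew nuts with shell,high,65,insect-pollinated nut
Cocoa beans,essential,95,midge-pollinated
Watermelons,essential,95,cucurbit requiring insect visits
Melons other,essential,95,cucurbit requiring insect visits
Pumpkins squash and gourds,essential,95,cucurbit requiring insect visits
Vanilla,essential,100,hand/insect pollination obligatory
Kiwi fruit,essential,95,dioecious fruit crop
Brazil nuts with shell,essential,95,bee-pollinated nut
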